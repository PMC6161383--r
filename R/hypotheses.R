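#' Create a modularity hypothesis
#'
#' A variational-modularity hypothesis is a named partition of trait indices
#' into disjoint putative modules. Traits left out of every set are treated as
#' non-modular background: they are hypothesised to integrate with nothing.
#'
#' @param name Human-readable hypothesis name.
#' @param sets A list of integer vectors of 1-based trait indices; sets must
#'   be disjoint, within `1..n_traits`, and at least one set must have two or
#'   more traits.
#' @param n_traits Total number of traits the hypothesis refers to.
#' @return An object of class `module_hypothesis`.
#' @examples
#' h <- module_hypothesis("limbs", list(7:10, 11:14))
#' connectivity_matrix(h)
#' @export
module_hypothesis <- function(name, sets, n_traits = 14L) {
  stopifnot(is.character(name), length(name) == 1, is.list(sets),
            length(sets) >= 1)
  sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
  idx <- unlist(sets)
  if (length(idx) == 0) stop("empty partition", call. = FALSE)
  if (anyDuplicated(idx) > 0) stop("partition sets must be disjoint", call. = FALSE)
  if (any(idx < 1L | idx > n_traits)) {
    stop("trait indices must lie in 1..", n_traits, call. = FALSE)
  }
  if (!any(lengths(sets) >= 2)) {
    stop("at least one module must contain two or more traits", call. = FALSE)
  }
  structure(list(name = name, sets = sets, n_traits = as.integer(n_traits)),
            class = "module_hypothesis")
}

#' @export
print.module_hypothesis <- function(x, ...) {
  cat("<module_hypothesis> ", x$name, "\n", sep = "")
  for (s in x$sets) cat("  {", paste(s, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' The eleven a priori hypotheses of body modularity
#'
#' Returns the standard set of eleven hypotheses for the 14-trait body:
#' the four basic anatomical modules (head/neck = traits 1-3, trunk = 4-6,
#' forelimbs = 7-10, hindlimbs = 11-14) and seven composites combining them.
#' In the single-region hypotheses (1-4) all remaining traits are treated as
#' non-modular background.
#'
#' @return A named list of 11 [module_hypothesis()] objects, in canonical
#'   order.
#' @examples
#' names(builtin_hypotheses())
#' builtin_hypotheses()[["trunk_forelimbs_hindlimbs"]]
#' @export
builtin_hypotheses <- function() {
  hn <- 1:3; tr <- 4:6; fl <- 7:10; hl <- 11:14
  defs <- list(
    head_neck                     = list(hn),
    trunk                         = list(tr),
    forelimbs                     = list(fl),
    hindlimbs                     = list(hl),
    head_neck_trunk               = list(hn, tr),
    trunk_forelimbs               = list(tr, fl),
    trunk_hindlimbs               = list(tr, hl),
    trunk_forelimbs_hindlimbs     = list(tr, fl, hl),
    head_neck_trunk_forelimbs     = list(hn, tr, fl),
    head_neck_trunk_hindlimbs     = list(hn, tr, hl),
    forelimbs_hindlimbs           = list(fl, hl)
  )
  purrr::imap(defs, function(sets, nm) module_hypothesis(nm, sets))
}

#' Binary connectivity matrix of a modularity hypothesis
#'
#' Encodes a hypothesis as a symmetric 0/1 trait-by-trait matrix with a one
#' wherever two distinct traits are hypothesised to be integrated (lie in the
#' same module) and zero elsewhere; the diagonal is zero.
#'
#' @param hypothesis A [module_hypothesis()].
#' @param n_traits Matrix dimension (defaults to the hypothesis's own).
#' @param labels Optional row/column names; defaults to [trait_names()] when
#'   `n_traits` is 14.
#' @return An `n_traits` x `n_traits` binary symmetric matrix.
#' @examples
#' sum(connectivity_matrix(builtin_hypotheses()$trunk)[lower.tri(diag(14))])
#' @export
connectivity_matrix <- function(hypothesis, n_traits = hypothesis$n_traits,
                                labels = NULL) {
  stopifnot(inherits(hypothesis, "module_hypothesis"))
  if (any(unlist(hypothesis$sets) > n_traits)) {
    stop("hypothesis indices exceed n_traits", call. = FALSE)
  }
  m <- matrix(0, n_traits, n_traits)
  for (s in hypothesis$sets) {
    if (length(s) >= 2) m[s, s] <- 1
  }
  diag(m) <- 0
  if (is.null(labels) && n_traits == 14L) labels <- trait_names()
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# module membership (head_neck/trunk/forelimb/hindlimb/none) per trait index
hypothesis_membership <- function(hypothesis) {
  mem <- rep(NA_integer_, hypothesis$n_traits)
  for (i in seq_along(hypothesis$sets)) mem[hypothesis$sets[[i]]] <- i
  mem
}
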