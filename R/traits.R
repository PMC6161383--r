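#' The 14 body traits and their anatomical modules
#'
#' The pipeline works on 14 linear body measurements (cm), numbered 1-14 in
#' the order used throughout: head length (HL), neck length (NL), neck
#' diameter (NB), trunk length (TL), chest width (BB), chest depth (BD),
#' forelimb length (FLL), forefoot length (TBL), forelimb hoof length (FHL),
#' forelimb hoof width (FHB), hindlimb length (HLL), hindfoot length (HFL),
#' hindlimb hoof length (HHL), hindlimb hoof width (HHB). Traits 1-3 form the
#' head/neck region, 4-6 the trunk, 7-10 the forelimb and 11-14 the hindlimb.
#'
#' @return `trait_names()` returns a character vector of the 14 trait
#'   abbreviations in canonical order. `trait_modules()` returns a named
#'   character vector mapping each trait to its anatomical region
#'   (`"head_neck"`, `"trunk"`, `"forelimb"`, `"hindlimb"`).
#' @examples
#' trait_names()
#' trait_modules()[["BD"]]
#' @export
trait_names <- function() {
  c("HL", "NL", "NB", "TL", "BB", "BD", "FLL", "TBL", "FHL", "FHB",
    "HLL", "HFL", "HHL", "HHB")
}

#' @rdname trait_names
#' @export
trait_modules <- function() {
  stats::setNames(
    rep(c("head_neck", "trunk", "forelimb", "hindlimb"), times = c(3, 3, 4, 4)),
    trait_names()
  )
}

#' Metadata factor levels recognised in trait tables
#' @keywords internal
#' @noRd
meta_levels <- function() {
  list(
    sex = c("male", "female"),
    age = c("subadult", "adult"),
    habitat = c("open", "closed")
  )
}

#' Validate a trait table
#'
#' Checks that a data frame carries the metadata columns (`id`, `population`,
#' `habitat`, `sex`, `age`) and all 14 trait columns, that trait values are
#' strictly positive and complete, that metadata levels are among the declared
#' factor levels, and that ids are unique. Unknown extra columns are kept with
#' a warning.
#'
#' @param table A data frame, or a path to a CSV file with the standard header.
#' @return A validated tibble with metadata columns as character and trait
#'   columns as double.
#' @examples
#' tab <- simulate_traits(sim_config(seed = 1))
#' tab <- validate_trait_table(tab)
#' @export
validate_trait_table <- function(table) {
  if (is.character(table) && length(table) == 1) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table))
  table <- tibble::as_tibble(table)
  meta <- c("id", "population", "habitat", "sex", "age")
  needed <- c(meta, trait_names())
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    stop("trait table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(table), needed)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    table <- table[needed]
  }
  if (anyDuplicated(table$id) > 0) {
    stop("duplicate individual ids: ",
         paste(utils::head(unique(table$id[duplicated(table$id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  lv <- meta_levels()
  for (col in names(lv)) {
    bad <- setdiff(unique(table[[col]]), lv[[col]])
    if (length(bad) > 0) {
      stop("unknown ", col, " level(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  for (tr in trait_names()) {
    v <- table[[tr]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("trait ", tr, " has missing or non-numeric values", call. = FALSE)
    }
    if (any(v <= 0)) {
      stop("trait ", tr, " has non-positive value(s) at id: ",
           paste(utils::head(table$id[v <= 0], 5), collapse = ", "),
           call. = FALSE)
    }
    table[[tr]] <- as.double(v)
  }
  table
}

# deterministic child seed for stage i under root seed (kept < 2^31 - 1)
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(i)) %% 2147483647L)
}

# run expr under a local RNG state seeded with `seed`; NULL = use current state
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
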