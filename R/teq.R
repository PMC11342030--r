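#' Benzo[a]pyrene toxic-equivalent concentrations
#'
#' Converts per-compound soil concentrations to a common toxicity scale by
#' multiplying each concentration C by the compound's toxicity equivalence
#' factor (TEF) relative to benzo[a]pyrene:
#'
#'   TEQ_i = C_i x TEF_i
#'
#' The total TEQ is the sum over compounds and expresses the burden of the
#' whole mixture in BaP-equivalents. Because every TEF is at most 1, the
#' total TEQ never exceeds the total concentration.
#'
#' @param concentrations Named numeric vector of concentrations in ug/g
#'   (names are registry abbreviations), or a `compound_summary`, in which
#'   case the compound means are used (the convention for site-level
#'   reporting).
#' @param registry A `pah_registry`.
#' @return A list of class `teq_result` with `per_compound` (named numeric
#'   vector of TEQs in ug/g BaP-equivalents) and `total` (their sum).
#' @examples
#' compute_teq(c(BaP = 5.39, BkF = 17.53))
#' @export
compute_teq <- function(concentrations, registry = pah_registry()) {
  if (inherits(concentrations, "compound_summary")) {
    x <- concentrations$mean
    names(x) <- concentrations$abbreviation
    concentrations <- x
  }
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    stop("concentrations must be named by compound abbreviation")
  }
  idx <- match(names(concentrations), registry$abbreviation)
  if (anyNA(idx)) {
    stop("unregistered compound(s): ",
         paste(names(concentrations)[is.na(idx)], collapse = ", "))
  }
  if (any(concentrations < 0, na.rm = TRUE)) {
    stop("concentrations must be nonnegative")
  }
  teq <- concentrations * registry$tef[idx]
  res <- list(per_compound = teq, total = sum(teq, na.rm = TRUE))
  class(res) <- "teq_result"
  res
}

#' Per-location TEQ totals
#'
#' Applies [compute_teq()] to every row of a concentration table,
#' returning the total TEQ at each sampling location. Useful for mapping
#' which locations carry the most toxic mixtures, as opposed to the
#' site-level TEQ of the mean profile.
#'
#' @param table A `concentration_table`.
#' @param registry A `pah_registry`.
#' @return Named numeric vector of per-location total TEQs (ug/g).
#' @export
teq_by_location <- function(table, registry = pah_registry()) {
  apply(table, 1, function(row) compute_teq(row, registry)$total)
}

#' @export
print.teq_result <- function(x, ...) {
  cat("TEQ (ug/g BaP-equivalents)\n")
  print(round(x$per_compound, 3))
  cat("total:", format(x$total), "\n")
  invisible(x)
}
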