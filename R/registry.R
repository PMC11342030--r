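#' PAH compound registry
#'
#' The registry holds the metadata every other computation relies on: the
#' compound abbreviation, full name, number of fused aromatic rings, the
#' molecular-weight class derived from the ring count, the toxicity
#' equivalence factor (TEF) relative to benzo[a]pyrene, and membership in
#' the seven-compound USEPA B2 carcinogenic set.
#'
#' The default registry covers the 16 USEPA priority PAHs commonly
#' quantified in soils, with the Nisbet & LaGoy (1992) TEF scheme:
#' 0.001 for Naph, Acy, Acen, Fln, Phe, Flt and Pyr; 0.01 for Ant, CHR and
#' BgP; 0.1 for BaA, BbF, BkF and IcP; and 1 for BaP and DhA.
#' Benzo[e]pyrene (BeP) is also shipped but disabled by default: it is
#' occasionally reported alongside the priority 16 yet has no assigned TEF,
#' and including it would change total-concentration denominators.
#'
#' The registry is data-driven: a CSV with columns `abbreviation`,
#' `full_name`, `n_rings`, `tef`, `carcinogenic` (and optionally `enabled`)
#' can be supplied to swap TEF schemes without code changes.
#'
#' @param path Path to a registry CSV. Defaults to the file shipped with
#'   the package.
#' @param include_bep Logical; include benzo[e]pyrene (TEF 0)? Default
#'   `FALSE` so that totals are taken over the 16 priority compounds.
#' @return A data frame of class `pah_registry` with one row per compound
#'   and columns `abbreviation`, `full_name`, `n_rings`, `mw_class`,
#'   `tef`, `carcinogenic`.
#' @examples
#' reg <- pah_registry()
#' reg[reg$abbreviation == "BaP", ]
#' @export
pah_registry <- function(path = NULL, include_bep = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "pah_registry.csv", package = "pahsoilrisk")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("registry file not found: ", path)
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("abbreviation", "full_name", "n_rings", "tef", "carcinogenic")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0) {
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"enabled" %in% names(reg)) reg$enabled <- TRUE
  if (!include_bep) {
    reg <- reg[reg$enabled, , drop = FALSE]
  }
  reg$enabled <- NULL
  validate_registry(reg)
  reg$mw_class <- mw_class_from_rings(reg$n_rings)
  rownames(reg) <- NULL
  class(reg) <- c("pah_registry", "data.frame")
  reg
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$abbreviation)) {
    stop("registry has duplicated abbreviations")
  }
  if (any(!reg$n_rings %in% 2:6)) {
    stop("n_rings must be in 2..6")
  }
  if (any(reg$tef < 0 | reg$tef > 1)) {
    stop("tef must lie in [0, 1]")
  }
  if (!is.logical(reg$carcinogenic)) {
    stop("carcinogenic must be logical")
  }
  invisible(reg)
}

#' Map ring counts to molecular-weight classes
#'
#' Low molecular weight (LMW) covers 2- and 3-ring compounds, middle
#' molecular weight (MMW) the 4-ring compounds, and high molecular weight
#' (HMW) the 5- and 6-ring compounds.
#'
#' @param n_rings Integer vector of fused aromatic ring counts (2 to 6).
#' @return Character vector in `{"LMW", "MMW", "HMW"}`.
#' @export
mw_class_from_rings <- function(n_rings) {
  if (any(!n_rings %in% 2:6)) stop("n_rings must be in 2..6")
  ifelse(n_rings <= 3, "LMW", ifelse(n_rings == 4, "MMW", "HMW"))
}

#' Look up one registry entry
#'
#' @param registry A `pah_registry`.
#' @param abbreviation Compound short code, e.g. `"BaP"`.
#' @return The one-row data frame for the compound.
#' @export
registry_entry <- function(registry, abbreviation) {
  stopifnot(length(abbreviation) == 1)
  i <- match(abbreviation, registry$abbreviation)
  if (is.na(i)) {
    stop("unknown compound abbreviation: ", abbreviation)
  }
  registry[i, , drop = FALSE]
}

#' Ring count of a registered compound
#'
#' @inheritParams registry_entry
#' @return Integer number of fused aromatic rings.
#' @export
ring_class <- function(registry, abbreviation) {
  registry_entry(registry, abbreviation)$n_rings
}

#' TEF of a registered compound
#'
#' @inheritParams registry_entry
#' @return The toxicity equivalence factor relative to benzo[a]pyrene.
#' @export
compound_tef <- function(registry, abbreviation) {
  registry_entry(registry, abbreviation)$tef
}
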