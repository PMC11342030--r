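#' Run the full characterization and risk pipeline
#'
#' Composes the whole analysis for one concentration table: summary
#' statistics per compound, TEQ on compound means, composition profiles
#' (ring number, molecular-weight class, carcinogenic aggregate), and the
#' multi-route cancer and non-cancer risk characterization for the
#' requested receptors. Deterministic for fixed inputs.
#'
#' @param table A `concentration_table`, or a path to a wide CSV which is
#'   read with [read_concentrations()].
#' @param registry A `pah_registry`.
#' @param factors A `slope_factors`.
#' @param receptors Character vector from `{"adult", "child"}`.
#' @param concentration_basis Which concentration drives the exposure
#'   equations: `"total"` (sum of compound means, the site-level
#'   convention), `"teq"` (total BaP-equivalent concentration), or a
#'   single compound abbreviation for a compound-specific assessment.
#' @param profiles Optional named list of `exposure_profile` overrides,
#'   keyed by receptor.
#' @return A list of class `report_bundle`: `summary` (per-compound table
#'   with TEQ column), `teq` (`teq_result`), `risk` (list of
#'   `risk_result` by receptor), `composition` (ring, mw, carcinogenic),
#'   `basis` (the concentration used and its name), `provenance`.
#' @examples
#' tab <- generate_site(default_profile(seed = 42))
#' rep <- run_pipeline(tab)
#' rep$risk$adult
#' @export
run_pipeline <- function(table, registry = pah_registry(),
                         factors = slope_factors(),
                         receptors = c("adult", "child"),
                         concentration_basis = "total",
                         profiles = NULL) {
  if (is.character(table) && length(table) == 1) {
    table <- read_concentrations(table, registry)
  }
  receptors <- match.arg(receptors, c("adult", "child"), several.ok = TRUE)

  summ <- withCallingHandlers(
    summarize_concentrations(table),
    warning = function(w) invokeRestart("muffleWarning")
  )
  teq <- compute_teq(summ, registry)
  total <- total_concentration(summ)

  basis_value <- if (identical(concentration_basis, "total")) {
    total
  } else if (identical(concentration_basis, "teq")) {
    teq$total
  } else if (concentration_basis %in% summ$abbreviation) {
    summ$mean[summ$abbreviation == concentration_basis]
  } else {
    stop("unknown concentration basis: ", concentration_basis)
  }

  risk <- lapply(receptors, function(rc) {
    p <- if (!is.null(profiles) && rc %in% names(profiles)) {
      profiles[[rc]]
    } else {
      exposure_profile(rc)
    }
    assess_risk(basis_value, p, factors)
  })
  names(risk) <- receptors

  out <- list(
    summary = summary_with_teq(summ, teq),
    teq = teq,
    risk = risk,
    composition = list(
      ring = ring_distribution(summ, registry),
      mw = mw_distribution(summ, registry),
      carcinogenic = carcinogenic_fraction(summ, registry)
    ),
    basis = list(name = concentration_basis, value = basis_value),
    provenance = list(
      n_locations = nrow(table),
      n_compounds = ncol(table),
      total_mean = total,
      package_version = as.character(utils::packageVersion("pahsoilrisk")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )
  class(out) <- "report_bundle"
  out
}

summary_with_teq <- function(summ, teq) {
  df <- as.data.frame(summ)
  df$teq <- unname(teq$per_compound[df$abbreviation])
  attr(df, "total_mean") <- attr(summ, "total_mean")
  attr(df, "total_teq") <- teq$total
  df
}

#' Risk table in report layout
#'
#' Flattens the risk results of a report bundle into one row per receptor
#' with route-specific ILCRs, the total, the EDI, the HQ and the
#' threshold flags. Values are full precision; apply [format_risk_table()]
#' for printed rounding.
#'
#' @param bundle A `report_bundle`.
#' @return A data frame, one row per receptor.
#' @export
risk_table <- function(bundle) {
  rows <- lapply(bundle$risk, function(r) {
    data.frame(receptor = r$receptor,
               ilcr_ingestion = r$ilcr_ingestion,
               ilcr_inhalation = r$ilcr_inhalation,
               ilcr_dermal = r$ilcr_dermal,
               ilcr_total = r$ilcr_total,
               edi = r$edi,
               hq = r$hq,
               cancer_exceeds = r$cancer_exceeds,
               noncancer_exceeds = r$noncancer_exceeds,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Printed rounding for the risk table
#'
#' ILCRs are rounded to 2 significant figures and the HQ to 2 decimals,
#' the conventional precision of published risk tables. Rounding happens
#' only here; every upstream value is carried at full precision.
#'
#' @param rt A data frame from [risk_table()].
#' @return The table with character columns formatted for printing.
#' @export
format_risk_table <- function(rt) {
  fmt <- function(x) signif(x, 2)
  data.frame(receptor = rt$receptor,
             ilcr_ingestion = fmt(rt$ilcr_ingestion),
             ilcr_inhalation = fmt(rt$ilcr_inhalation),
             ilcr_dermal = fmt(rt$ilcr_dermal),
             ilcr_total = fmt(rt$ilcr_total),
             hq = round(rt$hq, 2),
             stringsAsFactors = FALSE)
}

#' Write a report bundle to disk
#'
#' Exports the summary table (with TEQ column) and the risk table as CSV
#' or JSON, plus a JSON provenance block, under `dir`.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory, created if absent.
#' @param format `"csv"` or `"json"` for the tables.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rt <- risk_table(bundle)
  paths <- character(0)
  if (format == "csv") {
    p1 <- file.path(dir, "summary.csv")
    utils::write.csv(bundle$summary, p1, row.names = FALSE)
    p2 <- file.path(dir, "risk.csv")
    utils::write.csv(rt, p2, row.names = FALSE)
    paths <- c(p1, p2)
  } else {
    p1 <- file.path(dir, "summary.json")
    jsonlite::write_json(bundle$summary, p1, dataframe = "rows", digits = NA)
    p2 <- file.path(dir, "risk.json")
    jsonlite::write_json(rt, p2, dataframe = "rows", digits = NA)
    paths <- c(p1, p2)
  }
  p3 <- file.path(dir, "provenance.json")
  jsonlite::write_json(c(bundle$provenance,
                         list(composition = as.list(bundle$composition$mw),
                              basis = bundle$basis)),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p3))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("PAH site report: %d locations x %d compounds\n",
              x$provenance$n_locations, x$provenance$n_compounds))
  cat(sprintf("  total mean concentration: %.2f ug/g\n", x$provenance$total_mean))
  cat(sprintf("  total TEQ: %.2f ug/g BaP-eq\n", x$teq$total))
  carc <- x$composition$carcinogenic
  cat(sprintf("  carcinogenic PAHs: %.2f ug/g (%.2f%% of total)\n",
              carc$sum, carc$pct))
  cat("  risk (", paste(names(x$risk), collapse = ", "), "):\n", sep = "")
  print(format_risk_table(risk_table(x)))
  invisible(x)
}
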