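# canonical Mito Stress phase order
OCR_PHASES <- c("basal", "oligomycin", "FCCP", "rotenone_antimycin")

#' Construct a Mito Stress OCR trace for one well
#'
#' A phase-labelled oxygen consumption rate (OCR) trace from the Seahorse
#' Mito Stress Test: sequential measurement blocks at baseline, after
#' oligomycin (ATP-synthase inhibition), after FCCP (uncoupling) and after
#' rotenone/antimycin A (complex I/III inhibition). The canonical run has
#' three measurements per phase (12 timepoints); at least one per phase is
#' required, and phases must appear in the canonical order.
#'
#' @param well Well identifier.
#' @param group Experimental group label.
#' @param phase Character vector of phase labels (one of `"basal"`,
#'   `"oligomycin"`, `"FCCP"`, `"rotenone_antimycin"`), in measurement
#'   order.
#' @param ocr Numeric vector of OCR values (pmol O2/min), same length as
#'   `phase`.
#' @param protein Total protein in the well (micrograms), strictly
#'   positive.
#' @return A list of class `ocr_trace` with elements `well`, `group`,
#'   `measurements` (data frame: timepoint, phase, ocr), `protein`,
#'   `normalised`.
#' @export
ocr_trace <- function(well, group, phase, ocr, protein) {
  if (!is.numeric(protein) || length(protein) != 1L || !is.finite(protein) ||
      protein <= 0)
    coex_stop("nigracoex_bad_protein",
              "`protein` must be a single positive number")
  if (length(phase) != length(ocr))
    coex_stop("nigracoex_bad_argument",
              "`phase` and `ocr` must have the same length")
  if (!all(phase %in% OCR_PHASES))
    coex_stop("nigracoex_bad_argument",
              sprintf("unknown phase label(s): %s",
                      paste(setdiff(phase, OCR_PHASES), collapse = ", ")))
  if (!all(OCR_PHASES %in% phase))
    coex_stop("nigracoex_missing_phase",
              sprintf("missing phase(s): %s",
                      paste(setdiff(OCR_PHASES, phase), collapse = ", ")))
  # phases must form contiguous blocks in canonical order
  idx <- match(phase, OCR_PHASES)
  if (is.unsorted(idx))
    coex_stop("nigracoex_phase_order",
              "phases must appear in the order basal, oligomycin, FCCP, rotenone_antimycin")
  if (!all(is.finite(ocr)))
    coex_stop("nigracoex_non_finite", "OCR values must be finite")
  structure(list(well = well, group = group,
                 measurements = data.frame(
                   timepoint = seq_along(ocr),
                   phase = factor(phase, levels = OCR_PHASES),
                   ocr = as.numeric(ocr)),
                 protein = protein, normalised = FALSE),
            class = "ocr_trace")
}

#' Read a plate of OCR traces from a long-format table
#'
#' Expects columns `well`, `group`, `timepoint`, `phase`, `ocr`, `protein`
#' (one protein value per well). Rows are ordered by `timepoint` within
#' each well.
#'
#' @param path Path to the delimited file.
#' @param sep Field delimiter override.
#' @return Named list of `ocr_trace` objects, one per well.
#' @export
read_ocr_traces <- function(path, sep = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path, sep),
                           stringsAsFactors = FALSE)
  need <- c("well", "group", "timepoint", "phase", "ocr", "protein")
  if (!all(need %in% colnames(tab)))
    coex_stop("nigracoex_parse_error",
              sprintf("trace table needs columns: %s",
                      paste(need, collapse = ", ")))
  wells <- unique(tab$well)
  out <- lapply(wells, function(w) {
    rows <- tab[tab$well == w, ]
    rows <- rows[order(rows$timepoint), ]
    prot <- unique(rows$protein)
    if (length(prot) != 1L)
      coex_stop("nigracoex_parse_error",
                sprintf("well '%s' has inconsistent protein values", w))
    ocr_trace(w, rows$group[1L], rows$phase, rows$ocr, prot)
  })
  stats::setNames(out, wells)
}

#' Normalise an OCR trace to its protein content
#'
#' Divides every OCR value by the well's protein amount; units become
#' pmol O2/min per microgram.
#'
#' @param trace An `ocr_trace`.
#' @return The trace with normalised OCR values and `normalised = TRUE`.
#' @export
normalise_to_protein <- function(trace) {
  if (!inherits(trace, "ocr_trace"))
    coex_stop("nigracoex_bad_argument", "`trace` must be an ocr_trace")
  trace$measurements$ocr <- trace$measurements$ocr / trace$protein
  trace$normalised <- TRUE
  trace
}

phase_values <- function(trace, phase) {
  trace$measurements$ocr[trace$measurements$phase == phase]
}

#' Mito Stress respiratory parameters
#'
#' Derives the standard respiratory parameters from a phase-labelled OCR
#' trace. With the canonical aggregation (`aggregate = "last_min_max"`):
#' \describe{
#'   \item{non_mito}{minimum OCR after rotenone/antimycin A}
#'   \item{basal}{last basal OCR minus non_mito}
#'   \item{proton_leak}{minimum post-oligomycin OCR minus non_mito}
#'   \item{maximal}{maximum post-FCCP OCR minus non_mito}
#'   \item{atp_production}{last basal OCR minus minimum post-oligomycin OCR}
#'   \item{spare_capacity}{maximal minus basal}
#'   \item{coupling_efficiency}{atp_production / basal (dimensionless)}
#' }
#' By construction `basal = atp_production + proton_leak` exactly.
#' `aggregate = "mean"` replaces last/min/max with per-phase means. When
#' basal respiration is not positive, coupling efficiency is undefined and
#' returned as `NA` with a warning; the other parameters are still
#' returned.
#'
#' @param trace An `ocr_trace` (typically after [normalise_to_protein()]).
#' @param aggregate `"last_min_max"` (canonical Mito Stress definitions)
#'   or `"mean"` (per-phase means).
#' @return A list of class `mito_params` with the seven parameters plus
#'   `well`, `group`, `normalised`.
#' @examples
#' tr <- ocr_trace("A1", "ctrl",
#'                 rep(c("basal", "oligomycin", "FCCP",
#'                       "rotenone_antimycin"), each = 3),
#'                 c(100, 98, 96, 40, 38, 36, 150, 148, 146, 20, 19, 18),
#'                 protein = 1)
#' respiratory_parameters(tr)
#' @export
respiratory_parameters <- function(trace,
                                   aggregate = c("last_min_max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(trace, "ocr_trace"))
    coex_stop("nigracoex_bad_argument", "`trace` must be an ocr_trace")
  bas <- phase_values(trace, "basal")
  oli <- phase_values(trace, "oligomycin")
  fcc <- phase_values(trace, "FCCP")
  rot <- phase_values(trace, "rotenone_antimycin")
  if (aggregate == "last_min_max") {
    basal_ref <- bas[length(bas)]
    oligo_ref <- min(oli)
    fccp_ref <- max(fcc)
    non_mito <- min(rot)
  } else {
    basal_ref <- mean(bas)
    oligo_ref <- mean(oli)
    fccp_ref <- mean(fcc)
    non_mito <- mean(rot)
  }
  basal <- basal_ref - non_mito
  proton_leak <- oligo_ref - non_mito
  maximal <- fccp_ref - non_mito
  atp_production <- basal_ref - oligo_ref
  spare_capacity <- maximal - basal
  if (basal > 0) {
    coupling <- atp_production / basal
  } else {
    warning(sprintf("well '%s': basal respiration <= 0, coupling efficiency undefined",
                    trace$well), call. = FALSE)
    coupling <- NA_real_
  }
  structure(list(well = trace$well, group = trace$group,
                 non_mito = non_mito, basal = basal,
                 proton_leak = proton_leak, maximal = maximal,
                 atp_production = atp_production,
                 spare_capacity = spare_capacity,
                 coupling_efficiency = coupling,
                 normalised = trace$normalised, aggregate = aggregate),
            class = "mito_params")
}

#' @export
print.mito_params <- function(x, ...) {
  unit <- if (x$normalised) "pmol O2/min/ug" else "pmol O2/min"
  cat(sprintf("Respiratory parameters, well '%s' (group '%s'), %s:\n",
              x$well, x$group, unit))
  for (f in c("non_mito", "basal", "proton_leak", "maximal",
              "atp_production", "spare_capacity"))
    cat(sprintf("  %-18s %8.3f\n", f, x[[f]]))
  cat(sprintf("  %-18s %8.3f\n", "coupling_eff.", x$coupling_efficiency))
  invisible(x)
}

#' @export
as.data.frame.mito_params <- function(x, ...) {
  data.frame(well = x$well, group = x$group, non_mito = x$non_mito,
             basal = x$basal, proton_leak = x$proton_leak,
             maximal = x$maximal, atp_production = x$atp_production,
             spare_capacity = x$spare_capacity,
             coupling_efficiency = x$coupling_efficiency,
             stringsAsFactors = FALSE)
}

#' Corrected total cell fluorescence
#'
#' CTCF = integrated density - (area of the selected cell x mean
#' fluorescence of the background): the standard background-corrected
#' densitometric readout for single-cell fluorescence.
#'
#' @param integrated_density Integrated density of the selected cell.
#' @param cell_area Area of the selected cell (strictly positive).
#' @param background_mean_fluorescence Mean background fluorescence
#'   (non-negative).
#' @return Numeric CTCF value(s); vectorised over its arguments.
#' @examples
#' ctcf(1000, 50, 2)
#' @export
ctcf <- function(integrated_density, cell_area,
                 background_mean_fluorescence) {
  if (any(cell_area <= 0))
    coex_stop("nigracoex_bad_argument", "`cell_area` must be positive")
  if (any(background_mean_fluorescence < 0))
    coex_stop("nigracoex_bad_argument",
              "`background_mean_fluorescence` must be non-negative")
  integrated_density - cell_area * background_mean_fluorescence
}

#' Per-group mean and SEM of respiratory parameters
#'
#' Summarises per-well respiratory parameters as mean +/- SEM per group,
#' with SEM = sd / sqrt(n) over the n replicate wells. A single-well group
#' has an undefined SEM, reported as `NA`.
#'
#' @param params A list of `mito_params` objects, or a data frame of
#'   per-well parameters with a grouping column.
#' @param group_col Grouping column name (for the data-frame form).
#' @return Data frame with one row per group and parameter: `group`,
#'   `parameter`, `mean`, `sem`, `n`.
#' @export
group_summary <- function(params, group_col = "group") {
  df <- if (is.data.frame(params)) params else
    do.call(rbind, lapply(params, as.data.frame))
  if (!nrow(df))
    coex_stop("nigracoex_bad_argument", "no wells to summarise")
  if (!group_col %in% colnames(df))
    coex_stop("nigracoex_bad_argument",
              sprintf("no '%s' column", group_col))
  value_cols <- setdiff(colnames(df)[vapply(df, is.numeric, logical(1))],
                        group_col)
  rows <- list()
  for (g in unique(df[[group_col]])) {
    sub <- df[df[[group_col]] == g, , drop = FALSE]
    for (param in value_cols) {
      v <- sub[[param]]
      n <- sum(!is.na(v))
      if (n == 0L)
        coex_stop("nigracoex_bad_argument",
                  sprintf("group '%s' has no values for '%s'", g, param))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = param, mean = mean(v, na.rm = TRUE),
        sem = if (n > 1L) stats::sd(v, na.rm = TRUE) / sqrt(n) else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
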