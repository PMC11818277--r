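# Longitudinal RBC panels: endpoint extraction, anemia grading, group
# comparison and scale correlations.

#' RBC panel parameter names
#'
#' The seven complete-blood-count parameters handled by the pipeline, with
#' their conventional units: RBC (10^12/L), HGB (g/L), HCT (fraction), MCV
#' (fL), MCH (pg), MCHC (g/L), RDW (%).
#' @export
rbc_parameters <- c("RBC", "HGB", "HCT", "MCV", "MCH", "MCHC", "RDW")

#' Extract first / final / min-max endpoints from longitudinal panels
#'
#' For each sample and parameter: `first` and `final` are the earliest and
#' latest non-missing measurements by timestamp; `minmax` is the worst
#' value over the whole stay — the series minimum for every parameter
#' except RDW, whose maximum is the unfavourable direction. Parameters
#' missing at every time point yield `NA` endpoints. Tied timestamps are
#' broken by input order with a warning.
#'
#' @param panel long data.frame with columns `sample_id`, `timestamp`
#'   (numeric or orderable) and one column per parameter.
#' @param parameters parameter columns to extract (default
#'   [rbc_parameters] intersected with the available columns).
#' @return data.frame of class `endpoint_set`: `sample_id`, `parameter`,
#'   `first`, `final`, `minmax`.
#' @export
extract_endpoints <- function(panel, parameters = NULL) {
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  stopifnot(all(c("sample_id", "timestamp") %in% names(panel)))
  if (is.null(parameters)) {
    parameters <- intersect(rbc_parameters, names(panel))
  }
  missing_params <- setdiff(parameters, names(panel))
  if (length(missing_params) > 0L) {
    stop("panel lacks parameter column(s): ",
         paste(missing_params, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(paste(panel$sample_id, panel$timestamp))) {
    warning("tied timestamps within sample(s); input order used")
  }
  sids <- unique(panel$sample_id)
  ord <- order(match(panel$sample_id, sids), panel$timestamp)
  panel <- panel[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(panel)), factor(panel$sample_id, levels = sids))
  cols <- lapply(parameters, function(p) panel[[p]])
  ns <- length(sids); np <- length(parameters)
  first <- final <- minmax <- matrix(NA_real_, ns, np)
  for (s in seq_len(ns)) {
    rows_s <- idx[[s]]
    for (j in seq_len(np)) {
      v <- cols[[j]][rows_s]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      first[s, j] <- v[1]
      final[s, j] <- v[length(v)]
      minmax[s, j] <- if (parameters[j] == "RDW") max(v) else min(v)
    }
  }
  out <- data.frame(
    sample_id = rep(sids, each = np),
    parameter = rep(parameters, times = ns),
    first = as.vector(t(first)), final = as.vector(t(final)),
    minmax = as.vector(t(minmax)), stringsAsFactors = FALSE)
  class(out) <- c("endpoint_set", "data.frame")
  out
}

#' Grade anemia from a hemoglobin value
#'
#' Grades: `severe` (HGB < 80 g/L), `moderate` (80-109 g/L),
#' `below-reference` (above 109 g/L but below the sex-specific normal
#' reference of 130 g/L for men and 120 g/L for women), otherwise `none`.
#'
#' @param hgb hemoglobin in g/L (vectorised, > 0).
#' @param sex `"male"` or `"female"` per value; no default.
#' @return factor with levels `none`, `below-reference`, `moderate`,
#'   `severe`.
#' @export
classify_anemia <- function(hgb, sex) {
  if (any(is.na(hgb)) || any(hgb <= 0)) {
    stop("hgb must be positive and non-missing", call. = FALSE)
  }
  sex <- tolower(as.character(sex))
  if (length(sex) == 1L) sex <- rep(sex, length(hgb))
  if (any(!sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female' (no default)", call. = FALSE)
  }
  ref <- ifelse(sex == "male", 130, 120)
  grade <- rep("none", length(hgb))
  grade[hgb < ref] <- "below-reference"
  grade[hgb <= 109] <- "moderate"
  grade[hgb < 80] <- "severe"
  factor(grade, levels = c("none", "below-reference", "moderate", "severe"))
}

#' Flag samples whose endpoint crosses a cutoff
#'
#' Strict comparison: `below` flags `value < cutoff`, `above` flags
#' `value > cutoff`. Missing endpoints yield `NA` flags.
#'
#' @param endpoints result of [extract_endpoints()].
#' @param parameter one parameter name.
#' @param cutoff numeric cutoff.
#' @param direction `"below"` or `"above"`.
#' @param timepoint `"first"`, `"final"` or `"minmax"`.
#' @return named logical vector (names = sample ids).
#' @export
flag_threshold <- function(endpoints, parameter, cutoff,
                           direction = c("below", "above"),
                           timepoint = c("final", "first", "minmax")) {
  direction <- match.arg(direction)
  timepoint <- match.arg(timepoint)
  sub <- endpoints[endpoints$parameter == parameter, , drop = FALSE]
  if (nrow(sub) == 0L) stop("parameter not present: ", parameter, call. = FALSE)
  v <- sub[[timepoint]]
  flag <- if (direction == "below") v < cutoff else v > cutoff
  names(flag) <- sub$sample_id
  flag
}

#' Compare RBC endpoints between two groups (Mann-Whitney U + BH-FDR)
#'
#' Runs a two-sided Mann-Whitney U test per (parameter, timepoint) cell and
#' adjusts the p-values by Benjamini-Hochberg within this comparison
#' family. Cells where a parameter is missing in more than half of either
#' group are flagged `low_coverage`.
#'
#' @param endpoints result of [extract_endpoints()].
#' @param groups named binary group labels (names = sample ids).
#' @param parameters parameters to compare (default: all present).
#' @param timepoints subset of `c("first", "final", "minmax")`.
#' @param fdr_threshold FDR level for the significance flag.
#' @return data.frame: `parameter`, `timepoint`, `n1`, `n2`, `p`, `q`,
#'   `significant`, `low_coverage`.
#' @export
group_compare <- function(endpoints, groups, parameters = NULL,
                          timepoints = c("first", "final", "minmax"),
                          fdr_threshold = 0.05) {
  g <- as_binary_groups(groups[unique(endpoints$sample_id)])
  if (is.null(parameters)) parameters <- unique(endpoints$parameter)
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  rows <- list()
  for (param in parameters) {
    sub <- endpoints[endpoints$parameter == param, , drop = FALSE]
    gi <- groups[sub$sample_id]
    for (tp in timepoints) {
      v <- sub[[tp]]
      x <- v[gi == levels(g)[1] & !is.na(gi)]
      y <- v[gi == levels(g)[2] & !is.na(gi)]
      low_cov <- mean(is.na(x)) > 0.5 || mean(is.na(y)) > 0.5
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      p <- if (length(x) == 0L || length(y) == 0L) NA_real_ else
        mann_whitney_u(x, y, mode = "normal")$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, timepoint = tp, n1 = length(x), n2 = length(y),
        p = p, low_coverage = low_cov, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, fdr_threshold)
  out$q <- fdr$q
  out$significant <- fdr$reject
  out[c("parameter", "timepoint", "n1", "n2", "p", "q", "significant",
        "low_coverage")]
}

#' Spearman correlations between scale scores and RBC endpoints
#'
#' Correlates each score column with each parameter endpoint at each
#' timepoint; requires at least `min_pairs` complete pairs per cell. BH
#' q-values are computed over all computed cells.
#'
#' @param scores data.frame with `sample_id` and numeric score columns
#'   (e.g. neurological scale scores).
#' @param endpoints result of [extract_endpoints()].
#' @param timepoints subset of `c("first", "final", "minmax")`.
#' @param min_pairs minimum complete pairs per cell (default 5).
#' @param fdr_threshold FDR level for the significance flag.
#' @return data.frame: `score`, `parameter`, `timepoint`, `n`, `rho`, `p`,
#'   `q`, `significant`.
#' @export
scale_correlations <- function(scores, endpoints,
                               timepoints = c("first", "final"),
                               min_pairs = 5L, fdr_threshold = 0.05) {
  stopifnot("sample_id" %in% names(scores))
  score_cols <- setdiff(names(scores), "sample_id")
  timepoints <- match.arg(timepoints, c("first", "final", "minmax"),
                          several.ok = TRUE)
  rows <- list()
  for (sc in score_cols) {
    for (param in unique(endpoints$parameter)) {
      sub <- endpoints[endpoints$parameter == param, , drop = FALSE]
      s <- scores[[sc]][match(sub$sample_id, scores$sample_id)]
      for (tp in timepoints) {
        v <- sub[[tp]]
        ok <- !is.na(s) & !is.na(v)
        if (sum(ok) < min_pairs) next
        res <- spearman_rho(s[ok], v[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          score = sc, parameter = param, timepoint = tp, n = sum(ok),
          rho = res$estimate, p = res$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(score = character(0), parameter = character(0),
                      timepoint = character(0), n = integer(0),
                      rho = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, fdr_threshold)
  out$q <- fdr$q
  out$significant <- fdr$reject
  out
}
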