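# The in-silico design-selection funnel: metric ingestion, the
# self-consistency criterion, named campaign threshold presets, ddG
# ranking and cluster-representative selection. All threshold
# comparisons are strict (<, >); boundary values fail.

.metric_order <- c("ipae", "ddg", "sap", "cms", "rmsd_pred")

.metric_test <- function(metric, value, thr) {
  # max-semantics metrics must be strictly below, min-semantics strictly
  # above, their threshold
  switch(metric,
         ipae = value < thr,
         ddg = value < thr,
         sap = value < thr,
         rmsd_pred = value < thr,
         cms = value > thr,
         stop("unknown metric: ", metric))
}

#' Named campaign threshold presets
#'
#' The four design-campaign presets shipped with the package. Threshold
#' semantics: `ipae_max`, `ddg_max`, `sap_max`, `rmsd_pred_max` are
#' strict upper bounds; `cms_min` is a strict lower bound.
#'
#' * `mdm2`: iPAE < 0.3, ddG < -50 kcal/mol, SAP < 35, CMS > 300 A^2;
#'   ranking by ddG ascending, selection size 11.
#' * `gabarap`: iPAE < 0.13, ddG < -30, SAP < 35, CMS > 300; six target
#'   hotspots (residues 46, 48, 49, 50, 60, 63).
#' * `rbta`: iPAE < 0.4, ddG < -30, model-vs-prediction C-alpha r.m.s.d.
#'   < 1.5 A, CMS > 300; seven target hotspots (144, 202, 204, 206, 208,
#'   231, 269).
#' * `mcl1`: carries the documented metric set (ipae, ddg, sap, cms) but
#'   no numeric thresholds; configure them before use (the campaign's
#'   exact cutoffs are not part of the shipped registry).
#'
#' @param name One of `"mcl1"`, `"mdm2"`, `"gabarap"`, `"rbta"`.
#' @param ... Named threshold overrides (e.g. `ipae_max = 0.25`) and/or
#'   `selection_size`.
#' @return A `campaign_preset`: list with `name`, `thresholds`,
#'   `hotspots`, `ranking` and `selection_size`.
#' @export
campaign_preset <- function(name = c("mdm2", "gabarap", "rbta", "mcl1"),
                            ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    mdm2 = list(
      thresholds = list(ipae_max = 0.3, ddg_max = -50, sap_max = 35,
                        cms_min = 300),
      hotspots = NULL, ranking = "ddg", selection_size = 11L
    ),
    gabarap = list(
      thresholds = list(ipae_max = 0.13, ddg_max = -30, sap_max = 35,
                        cms_min = 300),
      hotspots = c("B:46", "B:48", "B:49", "B:50", "B:60", "B:63"),
      ranking = "ddg", selection_size = 13L
    ),
    rbta = list(
      thresholds = list(ipae_max = 0.4, ddg_max = -30,
                        rmsd_pred_max = 1.5, cms_min = 300),
      hotspots = c("B:144", "B:202", "B:204", "B:206", "B:208", "B:231",
                   "B:269"),
      ranking = "ddg", selection_size = 26L
    ),
    mcl1 = list(
      thresholds = list(ipae_max = NA_real_, ddg_max = NA_real_,
                        sap_max = NA_real_, cms_min = NA_real_),
      hotspots = NULL, ranking = "ddg", selection_size = 27L
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(base$thresholds)) base$thresholds[[nm]] <- dots[[nm]]
    else if (nm %in% c("selection_size", "ranking", "hotspots"))
      base[[nm]] <- dots[[nm]]
    else stop("unknown preset field: ", nm)
  }
  structure(c(list(name = name), base), class = "campaign_preset")
}

#' @export
print.campaign_preset <- function(x, ...) {
  thr <- vapply(x$thresholds, function(v)
    if (is.na(v)) "<configure>" else format(v), "")
  cat(sprintf("campaign_preset '%s': %s; rank by %s, select %d\n",
              x$name, paste(names(thr), thr, sep = "=", collapse = ", "),
              x$ranking, x$selection_size))
  invisible(x)
}

#' Read a campaign preset from a YAML config file
#'
#' The file carries key-value pairs: `name`, threshold keys
#' (`ipae_max`, `ddg_max`, `sap_max`, `cms_min`, `rmsd_pred_max`),
#' optional `hotspots` list, `ranking`, `selection_size`.
#'
#' @param path YAML file path.
#' @return A `campaign_preset`.
#' @export
read_preset <- function(path) {
  cfg <- yaml::read_yaml(path)
  nm <- cfg$name %||% "mdm2"
  cfg$name <- NULL
  do.call(campaign_preset, c(list(name = nm), cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Self-consistency of a designed backbone
#'
#' A design is self-consistent when at least one of its per-sequence
#' repredictions refolds with pLDDT strictly above `plddt_min` and
#' backbone r.m.s.d. strictly below `rmsd_max`. Both comparisons are
#' strict: boundary values fail.
#'
#' @param predictions Two-column matrix or data frame: pLDDT in `[0,1]`
#'   and backbone r.m.s.d. in Angstrom, one row per repredicted
#'   sequence.
#' @param plddt_min pLDDT lower threshold (default 0.8).
#' @param rmsd_max r.m.s.d. upper threshold in Angstrom (default 2.0).
#' @return Logical scalar.
#' @examples
#' self_consistency(cbind(c(0.85, 0.79), c(2.5, 1.0)))  # FALSE
#' @export
self_consistency <- function(predictions, plddt_min = 0.8, rmsd_max = 2.0) {
  p <- as.matrix(as.data.frame(predictions))
  if (nrow(p) == 0L) stop("prediction list must be non-empty")
  if (ncol(p) != 2L) stop("expected two columns: plddt, rmsd")
  any(p[, 1] > plddt_min & p[, 2] < rmsd_max)
}

.required_metrics <- function(preset) {
  thr <- preset$thresholds
  map <- c(ipae_max = "ipae", ddg_max = "ddg", sap_max = "sap",
           cms_min = "cms", rmsd_pred_max = "rmsd_pred")
  unname(map[names(thr)])
}

#' Apply a campaign preset to design records
#'
#' A record survives when every threshold of the preset passes its
#' strict comparison. Failures are attributed to the first failing
#' metric in the fixed evaluation order ipae, ddg, sap, cms, rmsd_pred,
#' so input count = survivors + sum of the tally.
#'
#' @param records Design-record data frame (see [ingest_metrics()]).
#' @param preset A [campaign_preset()]. All its thresholds must be set
#'   (not `NA`) and every tested metric present on every record.
#' @return List with `survivors` (data frame) and `report` (a
#'   `funnel_report` with per-stage counts and the failing-metric
#'   tally).
#' @export
apply_preset <- function(records, preset) {
  stopifnot(inherits(preset, "campaign_preset"))
  records <- as.data.frame(records)
  thr <- preset$thresholds
  if (any(vapply(thr, is.na, logical(1))))
    stop("preset '", preset$name, "' has unset threshold(s): ",
         paste(names(thr)[vapply(thr, is.na, logical(1))], collapse = ", "),
         "; configure them before filtering")
  metrics <- intersect(.metric_order, .required_metrics(preset))
  miss_col <- setdiff(metrics, names(records))
  if (length(miss_col))
    stop("records are missing metric column(s): ",
         paste(miss_col, collapse = ", "))
  n <- nrow(records)
  stages <- list()
  tally <- setNames(integer(length(metrics)), metrics)
  if (n > 0) {
    for (m in metrics) {
      bad <- is.na(records[[m]])
      if (any(bad))
        stop("design(s) missing tested metric '", m, "': ",
             paste(utils::head(records$design_id[bad], 5), collapse = ", "))
    }
  }
  alive <- rep(TRUE, n)
  thr_for <- function(m) switch(m,
                                ipae = thr$ipae_max, ddg = thr$ddg_max,
                                sap = thr$sap_max, cms = thr$cms_min,
                                rmsd_pred = thr$rmsd_pred_max)
  for (m in metrics) {
    before <- sum(alive)
    pass <- .metric_test(m, records[[m]], thr_for(m))
    newly_dead <- alive & !pass
    tally[m] <- sum(newly_dead)
    alive <- alive & pass
    stages[[m]] <- list(stage = m, input = before, surviving = sum(alive))
  }
  report <- structure(
    list(preset = preset$name, input = n, surviving = sum(alive),
         stages = stages, failing_tally = as.list(tally)),
    class = "funnel_report"
  )
  list(survivors = records[alive, , drop = FALSE], report = report)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("funnel_report (preset %s): %d -> %d designs\n",
              x$preset, x$input, x$surviving))
  for (s in x$stages)
    cat(sprintf("  %-10s %5d -> %5d  (failed here: %d)\n", s$stage,
                s$input, s$surviving, x$failing_tally[[s$stage]]))
  invisible(x)
}

#' Rank designs and select the top k
#'
#' Stable sort on a metric column (ascending by default, the convention
#' for ddG where more negative is better), ties broken by `design_id`,
#' then head-`k`.
#'
#' @param records Design-record data frame.
#' @param key Metric column to rank by.
#' @param k Number of designs to keep (`k` larger than the table returns
#'   everything).
#' @param decreasing Sort direction.
#' @return The top-`k` rows.
#' @export
rank_select <- function(records, key = "ddg", k, decreasing = FALSE) {
  records <- as.data.frame(records)
  if (!key %in% names(records)) stop("unknown ranking key: ", key)
  ord <- order(records[[key]], records$design_id,
               decreasing = c(decreasing, FALSE), method = "radix")
  utils::head(records[ord, , drop = FALSE], max(0L, as.integer(k)))
}

#' Pick top designs per structural cluster
#'
#' Within each cluster, ranks by `key` (ties by `design_id`) and keeps
#' `per_cluster` designs; output ordered by cluster id. This is the
#' diversity-preserving selection used after clustering filtered designs.
#'
#' @param records Design-record data frame; cluster labels are taken
#'   from `assignment` when given, else from a `cluster` column.
#' @param assignment Optional [greedy_cluster()] result whose labels are
#'   matched to `records` by position, or a vector of labels.
#' @param per_cluster Designs kept per cluster.
#' @param key Ranking metric.
#' @return Selected rows, ordered by cluster id.
#' @export
cluster_then_pick <- function(records, assignment = NULL, per_cluster = 1,
                              key = "ddg") {
  records <- as.data.frame(records)
  labels <- if (is.null(assignment)) records$cluster
  else if (inherits(assignment, "cluster_assignment")) assignment$labels
  else assignment
  if (is.null(labels)) stop("no cluster labels available")
  if (length(labels) != nrow(records))
    stop("cluster labels do not match the record table")
  if (anyNA(labels))
    stop("unlabeled record(s): ",
         paste(utils::head(records$design_id[is.na(labels)], 5),
               collapse = ", "))
  picked <- lapply(sort(unique(labels)), function(cl) {
    rank_select(records[labels == cl, , drop = FALSE], key = key,
                k = per_cluster)
  })
  do.call(rbind, picked)
}

.metric_columns <- c("plddt", "ipae", "rmsd_pred", "ddg", "sap", "cms")

#' Ingest a per-design metric table from CSV
#'
#' Reads a header-bearing CSV of per-design metrics as produced by
#' external predictors. Metric columns among `plddt`, `ipae`,
#' `rmsd_pred`, `ddg`, `sap`, `cms` are parsed as numbers; rows with
#' non-numeric cells in those columns are rejected and collected into a
#' report (attribute `"rejections"`), never silently dropped. When a
#' raw (unnormalized) interface PAE column is supplied, pass
#' `ipae_divisor` to convert it to the normalized `[0, 1]` form used by
#' the presets; otherwise the column is taken as already normalized.
#'
#' @param path CSV file path (UTF-8, header required; `design_id`
#'   column mandatory).
#' @param ipae_divisor Optional scalar; `ipae = ipae / ipae_divisor`.
#' @return Data frame of design records with attribute `rejections`
#'   (data frame of row numbers and reasons).
#' @export
ingest_metrics <- function(path, ipae_divisor = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"design_id" %in% names(raw))
    stop("metric table must carry a design_id column")
  metric_cols <- intersect(.metric_columns, names(raw))
  parsed <- raw
  bad_rows <- integer(0)
  reasons <- character(0)
  for (m in metric_cols) {
    v <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- which(is.na(v) & !is.na(raw[[m]]) & !(raw[[m]] %in% c("", "NA")))
    if (length(bad)) {
      bad_rows <- c(bad_rows, bad)
      reasons <- c(reasons, sprintf("non-numeric %s '%s'", m, raw[[m]][bad]))
    }
    parsed[[m]] <- v
  }
  if ("length" %in% names(parsed))
    parsed$length <- suppressWarnings(as.integer(parsed$length))
  keep <- !(seq_len(nrow(parsed)) %in% bad_rows)
  out <- parsed[keep, , drop = FALSE]
  if (!is.null(ipae_divisor)) {
    if (!is.numeric(ipae_divisor) || ipae_divisor <= 0)
      stop("`ipae_divisor` must be a positive number")
    out$ipae <- out$ipae / ipae_divisor
  }
  rej <- data.frame(row = bad_rows, reason = reasons,
                    stringsAsFactors = FALSE)
  attr(out, "rejections") <- rej[order(rej$row), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a design-record table to CSV
#'
#' Metric values round-trip through [ingest_metrics()] at full double
#' precision.
#'
#' @param records Design-record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path) {
  df <- as.data.frame(records)
  for (m in intersect(.metric_columns, names(df)))
    df[[m]] <- sprintf("%.17g", df[[m]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
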