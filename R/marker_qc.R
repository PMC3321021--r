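# Marker QC: peak scoring with a relative noise floor, fixed-width binning,
# replicate-based repeatability, the four-rule marker filter, and the
# replicate-discordance genotyping error rate.

#' Quality-control configuration for AFLP scoring and marker selection
#'
#' Defaults follow the standard protocol for capillary AFLP scoring: the
#' per-profile noise floor at 1% of the second-largest peak, a 50-unit
#' detection threshold, bins of at most 0.75 bases between 60 and 550 bases,
#' and an 81% marker repeatability cut-off. Threshold comparisons are
#' ">= keeps": a marker with repeatability exactly 0.81 survives ("less than
#' 81% ... excluded") and a peak of height exactly 50 is detected.
#'
#' @param relative_noise_fraction per-profile noise floor as a fraction of
#'   the second-largest peak height
#' @param detection_threshold absolute fluorescence detection threshold
#' @param size_range fragment size window in bases
#' @param max_bin_width maximum bin width in bases
#' @param min_repeatability minimum per-marker repeatability
#' @param drop_null_allele_only_bins drop bins with no present call among
#'   replicate rows (shared absences are homoplasy-prone)
#' @param drop_unconfirmed_bins drop bins without any present/present
#'   replicate pair
#' @param drop_monomorphic drop markers constant over the main samples
#' @return list of class `qc_config`
#' @export
qc_config <- function(relative_noise_fraction = 0.01,
                      detection_threshold = 50,
                      size_range = c(60, 550),
                      max_bin_width = 0.75,
                      min_repeatability = 0.81,
                      drop_null_allele_only_bins = TRUE,
                      drop_unconfirmed_bins = TRUE,
                      drop_monomorphic = TRUE) {
  if (relative_noise_fraction <= 0 || relative_noise_fraction >= 1) {
    stop("relative_noise_fraction must lie in (0, 1)")
  }
  if (min_repeatability <= 0 || min_repeatability > 1) {
    stop("min_repeatability must lie in (0, 1]")
  }
  if (length(size_range) != 2 || size_range[1] >= size_range[2]) {
    stop("size_range must be an ordered pair")
  }
  if (max_bin_width <= 0) stop("max_bin_width must be positive")
  structure(list(relative_noise_fraction = relative_noise_fraction,
                 detection_threshold = detection_threshold,
                 size_range = size_range, max_bin_width = max_bin_width,
                 min_repeatability = min_repeatability,
                 drop_null_allele_only_bins = drop_null_allele_only_bins,
                 drop_unconfirmed_bins = drop_unconfirmed_bins,
                 drop_monomorphic = drop_monomorphic),
            class = "qc_config")
}

#' Score peak profiles into a binary marker matrix
#'
#' Per profile, peaks below `relative_noise_fraction` times the height of the
#' second-largest peak are discarded as noise; peaks outside `size_range` are
#' excluded. Global fixed bins are then built greedily left-to-right over the
#' sorted union of retained peak sizes: a new bin opens whenever adding the
#' next peak would stretch the current bin beyond `max_bin_width`. A sample
#' scores present in a bin when one of its retained peaks with height at or
#' above `detection_threshold` falls inside the bin. Bins are named by their
#' size midpoint.
#'
#' Profiles with fewer than two peaks have no defined relative threshold;
#' they are scored all-absent with a warning.
#'
#' @param peaks data.frame with columns `sample`, `size_b`, `height`
#' @param config a [qc_config()]
#' @param replicate_suffix passed to replicate detection on the sample ids
#' @return a [marker_matrix()] with bins as loci
#' @export
score_profiles <- function(peaks, config = qc_config(),
                           replicate_suffix = "_rep[0-9]+$") {
  stopifnot(all(c("sample", "size_b", "height") %in% names(peaks)))
  samples <- unique(peaks$sample)
  by_sample <- split(peaks[c("size_b", "height")], factor(peaks$sample, samples))
  retained <- lapply(names(by_sample), function(id) {
    p <- by_sample[[id]]
    if (nrow(p) < 2) {
      warning("profile for sample '", id,
              "' has fewer than 2 peaks; scored all-absent")
      return(p[0, , drop = FALSE])
    }
    floor_h <- config$relative_noise_fraction * sort(p$height, decreasing = TRUE)[2]
    p <- p[p$height >= floor_h, , drop = FALSE]
    p[p$size_b >= config$size_range[1] & p$size_b <= config$size_range[2], ,
      drop = FALSE]
  })
  names(retained) <- names(by_sample)
  all_sizes <- sort(unlist(lapply(retained, `[[`, "size_b")))
  if (!length(all_sizes)) stop("no peaks retained in any profile")
  # greedy left-to-right binning over the sorted union of retained sizes
  bin_id <- integer(length(all_sizes))
  cur <- 1L; start <- all_sizes[1]
  for (i in seq_along(all_sizes)) {
    if (all_sizes[i] - start > config$max_bin_width) {
      cur <- cur + 1L
      start <- all_sizes[i]
    }
    bin_id[i] <- cur
  }
  lo <- tapply(all_sizes, bin_id, min)
  hi <- tapply(all_sizes, bin_id, max)
  mid <- (lo + hi) / 2
  locus_ids <- sprintf("bin_%.3f", mid)
  calls <- matrix(0L, length(samples), length(mid),
                  dimnames = list(samples, locus_ids))
  brk <- c(lo[1] - 1e-9, hi + 1e-9)  # right-open coverage of each bin
  for (id in samples) {
    p <- retained[[id]]
    p <- p[p$height >= config$detection_threshold, , drop = FALSE]
    if (!nrow(p)) next
    b <- findInterval(p$size_b, brk)
    b <- b[b >= 1 & b <= length(mid)]
    # findInterval assigns inter-bin gaps to the preceding bin; verify inside
    inside <- p$size_b[b >= 1 & b <= length(mid)] <= hi[b] + 1e-9 &
      p$size_b[b >= 1 & b <= length(mid)] >= lo[b] - 1e-9
    calls[id, unique(b[inside])] <- 1L
  }
  marker_matrix(calls, replicate_of = detect_replicates(samples, replicate_suffix))
}

evaluable_pairs <- function(x) {
  rp <- replicate_pairs(x)
  if (!nrow(rp)) stop("marker matrix has no replicate pairs")
  m <- unclass(x)
  list(a = m[rp$original, , drop = FALSE],
       b = m[rp$replicate, , drop = FALSE])
}

#' Estimate per-marker repeatability from replicate pairs
#'
#' Repeatability of a marker is the fraction of replicate pairs with
#' concordant calls among pairs where both calls are non-missing
#' (absent/absent pairs count as concordant). Each marker's replicate
#' evidence is also classified: `null_only` (every evaluable pair
#' absent/absent) and `confirmed_present` (at least one present/present
#' pair). Markers with no evaluable pair get `NA` repeatability and are
#' excluded from averaging.
#'
#' @param x a [marker_matrix()] with replicate rows
#' @return list of class `qc_report` with per-marker columns
#' @export
assess_repeatability <- function(x) {
  pr <- evaluable_pairs(x)
  both <- !is.na(pr$a) & !is.na(pr$b)
  n_eval <- colSums(both)
  conc <- colSums(both & (pr$a == pr$b), na.rm = TRUE)
  repeatability <- ifelse(n_eval > 0, conc / n_eval, NA_real_)
  any_present <- colSums(both & (pr$a == 1L | pr$b == 1L), na.rm = TRUE) > 0
  confirmed <- colSums(both & pr$a == 1L & pr$b == 1L, na.rm = TRUE) > 0
  per_marker <- data.frame(
    locus_id = colnames(x),
    n_pairs = as.integer(n_eval),
    repeatability = repeatability,
    null_only = n_eval > 0 & !any_present,
    confirmed_present = confirmed,
    error_rate = ifelse(n_eval > 0, 1 - conc / n_eval, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(per_marker = per_marker, dropped = NULL, retained = NULL),
            class = "qc_report")
}

#' Apply the four-rule marker selection filter
#'
#' Drops, in order: (1) markers with repeatability below
#' `min_repeatability`; (2) null-allele-only bins (no present call in any
#' evaluable replicate pair); (3) bins without a confirmed present/present
#' replicate pair; (4) markers monomorphic over the non-replicate samples.
#' The per-rule ledger conserves loci: dropped + retained = input.
#'
#' @param x a [marker_matrix()] with replicate rows
#' @param report a `qc_report` from [assess_repeatability()]
#' @param config a [qc_config()]
#' @return list with `markers` (filtered [marker_matrix()]) and `report`
#'   (the `qc_report` completed with the drop ledger and the mean error rate)
#' @export
select_markers <- function(x, report = assess_repeatability(x),
                           config = qc_config()) {
  pm <- report$per_marker
  stopifnot(identical(pm$locus_id, colnames(x)))
  rule <- rep(NA_character_, ncol(x))
  r1 <- !is.na(pm$repeatability) & pm$repeatability < config$min_repeatability
  rule[is.na(rule) & r1] <- "low_repeatability"
  if (config$drop_null_allele_only_bins) {
    rule[is.na(rule) & pm$null_only] <- "null_allele_only"
  }
  if (config$drop_unconfirmed_bins) {
    rule[is.na(rule) & !pm$confirmed_present] <- "no_confirmed_present"
  }
  if (config$drop_monomorphic) {
    main <- unclass(drop_replicates(x))
    mono <- apply(main, 2, function(col) {
      v <- unique(col[!is.na(col)])
      length(v) <= 1L
    })
    rule[is.na(rule) & mono] <- "monomorphic"
  }
  keep <- is.na(rule)
  if (!any(keep)) {
    stop("all loci removed by the QC filter; inspect thresholds")
  }
  dropped <- table(factor(rule[!keep],
                          levels = c("low_repeatability", "null_allele_only",
                                     "no_confirmed_present", "monomorphic")))
  filtered <- marker_matrix(unclass(x)[, keep, drop = FALSE],
                            replicate_of = attr(x, "replicate_of"))
  report$dropped <- as.data.frame(dropped, stringsAsFactors = FALSE,
                                  responseName = "n")
  names(report$dropped)[1] <- "rule"
  report$retained <- colnames(filtered)
  report$mean_error_rate <- genotyping_error_rate(filtered)
  list(markers = filtered, report = report)
}

#' Average genotyping error rate per marker
#'
#' Per-marker error rate is the replicate mismatch rate (discordant pairs /
#' evaluable pairs). Returned as a percentage. The default is the
#' unweighted mean over markers with at least one evaluable pair; the pooled
#' alternative (total mismatches / total comparisons) is available via
#' `method = "pooled"`.
#'
#' @param x a filtered [marker_matrix()] with replicate rows
#' @param method "per_marker" (unweighted mean) or "pooled"
#' @return error rate in percent
#' @export
genotyping_error_rate <- function(x, method = c("per_marker", "pooled")) {
  method <- match.arg(method)
  pr <- evaluable_pairs(x)
  both <- !is.na(pr$a) & !is.na(pr$b)
  n_eval <- colSums(both)
  if (!any(n_eval > 0)) stop("no evaluable replicate pairs")
  mism <- colSums(both & (pr$a != pr$b), na.rm = TRUE)
  if (method == "per_marker") {
    100 * mean((mism / n_eval)[n_eval > 0])
  } else {
    100 * sum(mism) / sum(n_eval)
  }
}
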