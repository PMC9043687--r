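#' Synthetic isospecific mimotope sets
#'
#' Builds a fixture of mimotope groups mimicking published panning
#' experiments with monoclonal antibodies on the same 7-mer library:
#' `n_sets` groups with sizes in `size_range` summing to `total`
#' sequences. Each group is one planted footprint family, so within-group
#' pairs share the LCS structure the calibration is meant to detect. The
#' fixture is synthetic and clearly labeled as such.
#'
#' @param n_sets number of antibody groups (default 49).
#' @param total total number of mimotopes over all groups (default 337).
#' @param size_range inclusive group-size range (default 2..27).
#' @param seed integer seed.
#' @return list of `isospecific_set` objects: `antibody_id`, `mimotopes`.
#' @export
synthetic_isospecific_sets <- function(n_sets = 49, total = 337,
                                       size_range = c(2, 27), seed = 7) {
  stopifnot(n_sets * size_range[1] <= total, n_sets * size_range[2] >= total)
  set.seed(seed)
  sizes <- rep(size_range[1], n_sets)
  # distribute the remaining mass uniformly at random under the cap
  rem <- total - sum(sizes)
  while (rem > 0) {
    open <- which(sizes < size_range[2])
    k <- if (length(open) == 1) open else sample(open, 1)
    sizes[k] <- sizes[k] + 1
    rem <- rem - 1
  }
  cfg <- synthetic_config(n_families = n_sets,
                          family_size_range = c(max(size_range[2], 2),
                                                max(size_range[2], 2)),
                          rng_seed = sample.int(1e6, 1))
  fams <- generate_families(cfg)
  lapply(seq_len(n_sets), function(i) {
    structure(list(antibody_id = sprintf("mAb%02d", i),
                   mimotopes = fams[[i]]$members[seq_len(sizes[i])]),
              class = "isospecific_set")
  })
}

#' Read isospecific sets from TSV
#'
#' Two tab-separated columns: `antibody_id`, `sequence`. Groups of fewer
#' than 2 sequences are skipped with a warning.
#'
#' @param path file path.
#' @export
read_isospecific_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("antibody_id", "sequence") %in% names(x)))
    stop("isospecific TSV needs columns 'antibody_id' and 'sequence'")
  sets <- split(x$sequence, x$antibody_id)
  small <- vapply(sets, length, integer(1)) < 2
  if (any(small))
    warning(sum(small), " group(s) with < 2 sequences skipped")
  sets <- sets[!small]
  mapply(function(id, seqs)
    structure(list(antibody_id = id, mimotopes = unique(seqs)),
              class = "isospecific_set"),
    names(sets), sets, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Build positive and negative sequence pairs for ROC calibration
#'
#' Positives are all unordered within-group pairs of isospecific
#' mimotopes; negatives pair each mimotope with one sequence drawn
#' uniformly from a reference (public) library.
#'
#' @param sets list of isospecific sets.
#' @param reference character vector of reference peptides.
#' @param seed integer seed for the negative draws.
#' @param negatives_per_mimotope reference draws per mimotope (default 1).
#' @return list with data.frames `positive` and `negative` (columns
#'   `s1`, `s2`) and the per-class counts.
#' @export
build_pairs <- function(sets, reference, seed = 1,
                        negatives_per_mimotope = 1) {
  set.seed(seed)
  usable <- vapply(sets, function(s) length(s$mimotopes) >= 2, logical(1))
  if (any(!usable))
    warning(sum(!usable), " set(s) of size < 2 skipped")
  sets <- sets[usable]
  pos <- do.call(rbind, lapply(sets, function(s) {
    p <- t(utils::combn(s$mimotopes, 2))
    data.frame(s1 = p[, 1], s2 = p[, 2], antibody_id = s$antibody_id,
               stringsAsFactors = FALSE)
  }))
  all_mims <- unlist(lapply(sets, `[[`, "mimotopes"))
  all_mims <- rep(all_mims, each = negatives_per_mimotope)
  neg <- data.frame(s1 = all_mims,
                    s2 = sample(reference, length(all_mims), replace = TRUE),
                    stringsAsFactors = FALSE)
  list(positive = pos, negative = neg,
       n_positive = nrow(pos), n_negative = nrow(neg))
}

#' ROC curve of a metric for isospecific-pair detection
#'
#' Sweeps the threshold over all observed distance values, calling a pair
#' positive when its distance is `<= t` (for `pwa` the score is negated
#' first so that smaller always means more similar). AUC by the trapezoid
#' rule.
#'
#' @param metric metric id (see [seq_metric()]).
#' @param pairs output of [build_pairs()], or `NULL` when `d_pos`/`d_neg`
#'   are given directly.
#' @param recoded use the property-recoded variant.
#' @param d_pos,d_neg precomputed distances (optional).
#' @return object of class `igome_roc`: `metric`, `points` (threshold,
#'   sensitivity, specificity), `auc`, `youden_cutoff`.
#' @export
roc_metric <- function(metric = "lcs", pairs = NULL, recoded = FALSE,
                       d_pos = NULL, d_neg = NULL) {
  if (is.null(d_pos)) {
    stopifnot(!is.null(pairs))
    d_pos <- seq_metric(metric, pairs$positive$s1, pairs$positive$s2,
                        recoded = recoded)
    d_neg <- seq_metric(metric, pairs$negative$s1, pairs$negative$s2,
                        recoded = recoded)
  }
  if (length(d_pos) == 0 || length(d_neg) == 0)
    stop("both pair classes must be non-empty")
  if (metric == "pwa") { d_pos <- -d_pos; d_neg <- -d_neg }
  if (length(unique(c(d_pos, d_neg))) == 1) {
    warning("all scores identical; AUC is 0.5")
    pts <- data.frame(threshold = d_pos[1], sensitivity = 1, specificity = 0)
    return(structure(list(metric = metric, points = pts, auc = 0.5,
                          youden_cutoff = d_pos[1]), class = "igome_roc"))
  }
  th <- sort(unique(c(d_pos, d_neg)))
  sens <- vapply(th, function(t) mean(d_pos <= t), numeric(1))
  spec <- vapply(th, function(t) mean(d_neg > t), numeric(1))
  # trapezoid over (FPR, TPR), anchored at (0,0) and (1,1)
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
  youden <- th[which.max(sens + spec - 1)]
  structure(list(metric = metric,
                 points = data.frame(threshold = th, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, youden_cutoff = youden),
            class = "igome_roc")
}

#' @export
print.igome_roc <- function(x, ...) {
  cat(sprintf("ROC [%s]: AUC = %.3f, Youden cutoff = %g (%d points)\n",
              x$metric, x$auc, x$youden_cutoff, nrow(x$points)))
  invisible(x)
}

#' Bootstrap the AUC over repeated negative draws
#'
#' Repeats the negative pairing with fresh uniform reference draws and
#' recomputes every requested metric's ROC on the same draw, giving a
#' paired comparison of metrics across bootstrap rounds.
#'
#' @param metrics character vector of metric ids; append `"_h"` for the
#'   property-recoded variant (e.g. `"lcs_h"`).
#' @param sets isospecific sets.
#' @param reference reference peptide library (character vector).
#' @param n_samples bootstrap rounds (default 20).
#' @param seed master seed.
#' @return data.frame `metric`, `sample`, `auc`; attribute `summary` with
#'   per-metric quantiles.
#' @export
bootstrap_auc <- function(metrics, sets, reference, n_samples = 20,
                          seed = 1) {
  res <- do.call(rbind, lapply(seq_len(n_samples), function(b) {
    pairs <- build_pairs(sets, reference, seed = seed + b)
    do.call(rbind, lapply(metrics, function(m) {
      recoded <- grepl("_h$", m)
      data.frame(metric = m, sample = b,
                 auc = roc_metric(sub("_h$", "", m), pairs,
                                  recoded = recoded)$auc,
                 stringsAsFactors = FALSE)
    }))
  }))
  smry <- do.call(rbind, lapply(split(res$auc, res$metric), function(a)
    data.frame(mean = mean(a), q25 = stats::quantile(a, 0.25),
               median = stats::median(a), q75 = stats::quantile(a, 0.75))))
  smry$metric <- rownames(smry)
  attr(res, "summary") <- smry
  res
}

#' Select the graph edge criterion from an LCS ROC
#'
#' The Youden-optimal LCS threshold tends to be permissive; the edge
#' criterion is instead the smallest LCS length whose specificity exceeds
#' a floor (default 0.9), trading sensitivity for stricter isospecific
#' pairing. Both thresholds are reported.
#'
#' @param roc an `igome_roc` computed with the `lcs` metric on 7-mers.
#' @param specificity_floor minimal acceptable specificity.
#' @return list: `lcs_threshold` (minimal common-subsequence length),
#'   `max_distance` (the equivalent LCS-distance cutoff),
#'   `youden_lcs`, `achieved_specificity`.
#' @export
select_edge_criterion <- function(roc, specificity_floor = 0.9) {
  stopifnot(inherits(roc, "igome_roc"), roc$metric == "lcs")
  pts <- roc$points
  # distance d between 7-mers <=> shared LCS of (14 - d) / 2 letters
  lcs_of <- function(d) (14 - d) / 2
  ok <- pts$specificity > specificity_floor
  if (!any(ok)) {
    warning("specificity floor unreachable; returning strictest threshold")
    chosen <- min(pts$threshold)
  } else {
    # Youden-optimal among the thresholds meeting the floor; ties resolved
    # toward the more permissive (smaller-LCS) threshold
    j <- pts$sensitivity + pts$specificity - 1
    j[!ok] <- -Inf
    cand <- which(j == max(j))
    chosen <- max(pts$threshold[cand])
  }
  list(lcs_threshold = lcs_of(chosen),
       max_distance = chosen,
       youden_lcs = lcs_of(roc$youden_cutoff),
       achieved_specificity = pts$specificity[match(chosen, pts$threshold)])
}
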