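# Shared fixture builders; everything is generated in code at test time.

# Truth-mask segmentation object for a generated phantom (tubule and
# surface parts of the membrane kept disjoint).
truth_masks <- function(ph) {
  segmentation_masks(
    membrane_mask = ph$truth$tubule_mask | ph$truth$surface_mask,
    cell_mask = ph$truth$cell_mask,
    tubule_mask = ph$truth$tubule_mask & !ph$truth$surface_mask,
    surface_mask = ph$truth$surface_mask)
}

# Match estimated segments to ground-truth cells by majority overlap and
# return the per-cell absolute axial orientation errors (degrees).
orientation_errors <- function(truth, label_map, orientations) {
  n <- length(truth$true_orientations_deg)
  errs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tm <- truth$label_map == i
    ov <- table(label_map$labels[tm])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) next
    est_id <- as.integer(names(ov)[which.max(ov)])
    est_ang <- orientations$orientation_deg[orientations$cell_id == est_id]
    if (!length(est_ang) || is.na(est_ang)) next
    d <- abs(est_ang - truth$true_orientations_deg[i]) %% 180
    errs[i] <- min(d, 180 - d)
  }
  errs
}

# Mean per-cell Jaccard overlap of estimated segments with truth cells.
mosaic_jaccard <- function(truth, label_map) {
  n <- length(truth$true_orientations_deg)
  j <- numeric(n)
  for (i in seq_len(n)) {
    tm <- truth$label_map == i
    ov <- table(label_map$labels[tm])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) { j[i] <- 0; next }
    est_id <- as.integer(names(ov)[which.max(ov)])
    em <- label_map$labels == est_id
    j[i] <- sum(em & tm) / sum(em | tm)
  }
  j
}
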