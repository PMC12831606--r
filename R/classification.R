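#' Assign target and excluded labels from beamlet geometry
#'
#' A cell overlaps a beamlet (is "wholly or partially within its radius")
#' when the distance between the cell centroid and the beamlet centre is
#' less than the beamlet radius plus the cell radius. For each beamlet, the
#' overlapping cell whose centroid is nearest the beamlet centre becomes the
#' target (ties broken toward the lowest cell index); the remaining
#' overlapping cells are excluded from all downstream analysis. Beamlets are
#' processed in index order and a cell already claimed as a target is not
#' reconsidered; a beamlet with no overlapping cell is left unmatched with a
#' warning.
#'
#' @param beamlets Tibble with `beamlet`, `x`, `y`, `radius`.
#' @param cells Tibble with `cell`, `x`, `y`, `radius` (a
#'   [make_population()] works directly).
#' @return A tibble `cell`, `label` (`"target"`, `"excluded"`, `"none"`),
#'   `beamlet` (matched beamlet for targets, `NA` otherwise), `dist`
#'   (centroid distance to that beamlet).
#' @export
assign_targets <- function(beamlets, cells) {
  if (any(beamlets$radius <= 0)) {
    abort("Beamlet radius must be positive.", class = "optodesens_argument_error")
  }
  label <- setNames(rep("none", nrow(cells)), cells$cell)
  matched <- setNames(rep(NA_integer_, nrow(cells)), cells$cell)
  dist_to <- setNames(rep(NA_real_, nrow(cells)), cells$cell)
  for (b in seq_len(nrow(beamlets))) {
    d <- sqrt((cells$x - beamlets$x[b])^2 + (cells$y - beamlets$y[b])^2)
    within <- d < beamlets$radius[b] + cells$radius
    cand <- which(within & label != "target")
    if (length(cand) == 0) {
      if (!any(within)) {
        warn(sprintf("Beamlet %s has no overlapping cell; left unmatched.",
                     beamlets$beamlet[b]))
      }
      next
    }
    tgt <- cand[order(d[cand], cells$cell[cand])][1]
    label[tgt] <- "target"
    matched[tgt] <- beamlets$beamlet[b]
    dist_to[tgt] <- d[tgt]
    others <- setdiff(which(within), tgt)
    newly_excluded <- others[label[others] == "none"]
    label[newly_excluded] <- "excluded"
    dist_to[newly_excluded] <- d[newly_excluded]
  }
  tibble(cell = cells$cell, label = unname(label),
         beamlet = unname(matched), dist = unname(dist_to))
}

# Concatenated dF/F window of one cell over the given trials, as a named
# vector aligned on (trial, t_rel).
window_vector <- function(dff, id, trials = NULL) {
  d <- filter(dff, .data$cell == id)
  if (!is.null(trials)) d <- filter(d, .data$trial %in% trials)
  d <- arrange(d, .data$trial, .data$t_rel)
  setNames(d$dff, paste(d$trial, signif(d$t_rel, 10)))
}

cor_or_null <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3) return(NULL)
  a <- a[keep]; b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NULL)
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Classify non-target cells as excited, inhibited or non-responders
#'
#' A non-target (and non-excluded) cell is excited or inhibited if its
#' delta-F/F is significantly Pearson-correlated with at least one target
#' cell both (i) across all trials' windows concatenated and (ii) across the
#' trial-1 window alone (two-sided p < 0.05 each), with both coefficients
#' sharing a sign — the trial-1 requirement ensures that correlated cells
#' are active on trial 1, so trial-1 vs trial-10 comparisons are meaningful
#' for them. The reported coefficient (whose sign sets excited vs inhibited)
#' is the all-trials correlation of the qualifying target with the largest
#' absolute coefficient. Windows span the 2 s around stimulation
#' (`[-1, +1)` s relative to onset). Zero-variance windows skip that
#' cell-target pair with a warning.
#'
#' @param dff A [trial_dff()] table containing at least `[-1, +1)` s around
#'   each onset.
#' @param target_assignment An [assign_targets()] table.
#' @param alpha Significance level for both correlation tests.
#' @param window Window (seconds relative to onset) used for correlation.
#' @return A tibble `cell`, `label` (`excited` / `inhibited` /
#'   `non_responder`), `r`, `p_all`, `p_trial1`, `target` (qualifying
#'   target cell id) for every non-target, non-excluded cell.
#' @export
classify_network <- function(dff, target_assignment, alpha = 0.05,
                             window = c(-1, 1)) {
  if (length(unique(dff$trial)) < 2) {
    abort("At least 2 trials are required for network classification.",
          class = "optodesens_argument_error")
  }
  d <- filter(dff, .data$t_rel >= window[1], .data$t_rel < window[2])
  targets <- target_assignment$cell[target_assignment$label == "target"]
  others <- target_assignment$cell[target_assignment$label == "none"]
  tgt_all <- map(targets, ~window_vector(d, .x))
  tgt_t1 <- map(targets, ~window_vector(d, .x, trials = 1))
  rows <- map(others, function(id) {
    v_all <- window_vector(d, id)
    v_t1 <- window_vector(d, id, trials = 1)
    best <- NULL
    for (j in seq_along(targets)) {
      c_all <- cor_or_null(v_all, tgt_all[[j]])
      c_t1 <- cor_or_null(v_t1, tgt_t1[[j]])
      if (is.null(c_all) || is.null(c_t1)) {
        warn(sprintf(
          "Zero-variance or too-short window for cell %s vs target %s; pair skipped.",
          id, targets[j]))
        next
      }
      qualifies <- c_all$p < alpha && c_t1$p < alpha &&
        sign(c_all$r) == sign(c_t1$r)
      if (qualifies && (is.null(best) || abs(c_all$r) > abs(best$r))) {
        best <- list(r = c_all$r, p_all = c_all$p, p_t1 = c_t1$p,
                     target = targets[j])
      }
    }
    if (is.null(best)) {
      tibble(cell = id, label = "non_responder", r = NA_real_,
             p_all = NA_real_, p_trial1 = NA_real_, target = NA_integer_)
    } else {
      tibble(cell = id, label = if (best$r > 0) "excited" else "inhibited",
             r = best$r, p_all = best$p_all, p_trial1 = best$p_t1,
             target = best$target)
    }
  })
  list_rbind(rows)
}

#' Full cell partition for a session
#'
#' Runs [assign_targets()] on the session's beamlets, then
#' [classify_network()] on the remaining cells, producing the complete
#' partition target / excluded / excited / inhibited / non_responder.
#'
#' @param session An `opto_session`.
#' @param dff Optional precomputed [trial_dff()] (saves recomputation).
#' @param alpha Significance level for the correlation tests.
#' @return A tibble `cell`, `label`, `r`, `p_all`, `p_trial1`, `beamlet`,
#'   `target`; one row per cell (a partition).
#' @export
classify_cells <- function(session, dff = NULL, alpha = 0.05) {
  if (is.null(dff)) dff <- trial_dff(session, pre = 1, post = 2)
  ta <- assign_targets(session$beamlets, session$population)
  net <- classify_network(dff, ta, alpha = alpha)
  geo <- filter(ta, .data$label != "none")
  geo <- mutate(geo, r = NA_real_, p_all = NA_real_, p_trial1 = NA_real_,
                target = NA_integer_)
  net <- mutate(net, beamlet = NA_integer_, dist = NA_real_)
  out <- bind_rows(select(geo, "cell", "label", "r", "p_all", "p_trial1",
                          "beamlet", "target"),
                   select(net, "cell", "label", "r", "p_all", "p_trial1",
                          "beamlet", "target"))
  arrange(out, .data$cell)
}

#' Count cells per class
#'
#' @param labels A [classify_cells()] (or [assign_targets()]) table.
#' @return A tibble `label`, `n`; counts sum to the number of cells.
#' @export
partition_summary <- function(labels) {
  count(labels, .data$label, name = "n")
}
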