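group_strata <- function(groups) {
  c(list(OVERALL = unique(groups)),
    stats::setNames(as.list(intersect(GROUPS, groups)), intersect(GROUPS, groups)))
}

#' Summarize a scored study into the report tables
#'
#' Aggregates per-annotation metric records and change records into the four
#' study-level tables, per expertise group and overall:
#'
#' * `table1` — centroid-inclusion counts and proportions pre/post AI
#'   assistance, with a two-sided Fisher exact p per row.
#' * `table2` — mean and SD of the DICE score (as percent) pre/post, the
#'   difference of the unrounded means, and a paired Wilcoxon signed-rank p
#'   (pairing each participant-image combination).
#' * `table3` — mean and SD of the union-normalized false-positive and
#'   false-negative percentages pre/post; the change columns are post minus
#'   pre for both the mean and the SD.
#' * `change_summary` — how many annotations were changed after AI
#'   assistance and the proportions whose DICE improved / worsened / stayed.
#' * `mcnemar_participants` — per-participant "centroid hit on all images"
#'   indicators pre/post compared with the exact McNemar test.
#'
#' Means and SDs are taken over all participant-image records in the stratum
#' (36 per group, 144 overall in the full design), with the sample (n-1) SD.
#' Only complete PRE/POST pairs enter; incomplete pairs are dropped with a
#' message.
#'
#' @param metrics Per-annotation records from [evaluate_dataset()].
#' @param changes Change records from [evaluate_dataset()].
#' @return List of data frames `table1`, `table2`, `table3`,
#'   `change_summary`, `mcnemar_participants`.
#' @export
summarize_study <- function(metrics, changes) {
  need <- c("annotator_id", "group", "image_id", "round", "dice",
            "fp_frac", "fn_frac", "centroid_hit")
  stopifnot(all(need %in% names(metrics)))
  for (g in unique(metrics$group))
    if (!any(metrics$group == g & metrics$round == "PRE") ||
        !any(metrics$group == g & metrics$round == "POST"))
      stop("group with no complete records: ", g)

  key <- paste(metrics$annotator_id, metrics$image_id, sep = "\r")
  pre <- metrics[metrics$round == "PRE", ]
  post <- metrics[metrics$round == "POST", ]
  pre_key <- key[metrics$round == "PRE"]
  post_key <- key[metrics$round == "POST"]
  common <- intersect(pre_key, post_key)
  n_drop <- (nrow(pre) - length(common)) + (nrow(post) - length(common))
  if (n_drop > 0)
    message(sprintf("summarize_study: excluded %d record(s) without a PRE/POST partner",
                    n_drop))
  pre <- pre[match(common, pre_key), ]
  post <- post[match(common, post_key), ]

  strata <- group_strata(pre$group)
  pct <- function(x) 100 * x

  table1 <- do.call(rbind, lapply(names(strata), function(s) {
    i <- pre$group %in% strata[[s]]
    n <- sum(i)
    h0 <- sum(pre$centroid_hit[i]); h1 <- sum(post$centroid_hit[i])
    p <- if (h0 == h1 && h0 == n) NA_real_ else
      fisher_exact_2x2(matrix(c(h0, n - h0, h1, n - h1), 2L, byrow = TRUE))$p_value
    data.frame(group = s, pre_hits = h0, post_hits = h1, n = n,
               pre_pct = pct(h0 / n), post_pct = pct(h1 / n),
               difference_pct = pct((h1 - h0) / n), p_value = p,
               stringsAsFactors = FALSE)
  }))

  table2 <- do.call(rbind, lapply(names(strata), function(s) {
    i <- pre$group %in% strata[[s]]
    m0 <- mean(pre$dice[i]); m1 <- mean(post$dice[i])
    w <- wilcoxon_signed_rank(pre$dice[i], post$dice[i])
    data.frame(group = s, n = sum(i),
               pre_mean = pct(m0), pre_sd = pct(stats::sd(pre$dice[i])),
               post_mean = pct(m1), post_sd = pct(stats::sd(post$dice[i])),
               difference = pct(m1 - m0), p_value = w$p_value,
               stringsAsFactors = FALSE)
  }))

  table3 <- do.call(rbind, lapply(names(strata), function(s) {
    i <- pre$group %in% strata[[s]]
    st <- function(x) c(mean = mean(x), sd = stats::sd(x))
    fp0 <- st(pct(pre$fp_frac[i])); fp1 <- st(pct(post$fp_frac[i]))
    fn0 <- st(pct(pre$fn_frac[i])); fn1 <- st(pct(post$fn_frac[i]))
    data.frame(group = s, n = sum(i),
               fp_pre_mean = fp0[["mean"]], fp_pre_sd = fp0[["sd"]],
               fp_post_mean = fp1[["mean"]], fp_post_sd = fp1[["sd"]],
               fp_change_mean = fp1[["mean"]] - fp0[["mean"]],
               fp_change_sd = fp1[["sd"]] - fp0[["sd"]],
               fn_pre_mean = fn0[["mean"]], fn_pre_sd = fn0[["sd"]],
               fn_post_mean = fn1[["mean"]], fn_post_sd = fn1[["sd"]],
               fn_change_mean = fn1[["mean"]] - fn0[["mean"]],
               fn_change_sd = fn1[["sd"]] - fn0[["sd"]],
               stringsAsFactors = FALSE)
  }))

  stopifnot(all(c("group", "annotation_changed", "dice_outcome") %in% names(changes)))
  change_summary <- do.call(rbind, lapply(names(strata), function(s) {
    ch <- changes[changes$group %in% strata[[s]], ]
    n <- nrow(ch)
    data.frame(group = s, n = n, changed = sum(ch$annotation_changed),
               changed_pct = pct(sum(ch$annotation_changed) / n),
               improved_pct = pct(mean(ch$dice_outcome == "IMPROVED")),
               worsened_pct = pct(mean(ch$dice_outcome == "WORSENED")),
               unchanged_pct = pct(mean(ch$dice_outcome == "UNCHANGED")),
               stringsAsFactors = FALSE)
  }))

  # per-participant: centroid hit on every image, pre vs post, exact McNemar
  part <- unique(pre$annotator_id)
  all_hit <- function(df) vapply(part, function(a)
    all(df$centroid_hit[df$annotator_id == a]), NA)
  hit0 <- all_hit(pre); hit1 <- all_hit(post)
  pgroup <- pre$group[match(part, pre$annotator_id)]
  mcnemar_participants <- do.call(rbind, lapply(names(strata), function(s) {
    i <- pgroup %in% strata[[s]]
    b <- sum(hit0[i] & !hit1[i]); cc <- sum(!hit0[i] & hit1[i])
    data.frame(group = s, n = sum(i),
               pre_all_hit = sum(hit0[i]), post_all_hit = sum(hit1[i]),
               discordant_b = b, discordant_c = cc,
               p_value = mcnemar_exact(b, cc)$p_value,
               stringsAsFactors = FALSE)
  }))

  list(table1 = table1, table2 = table2, table3 = table3,
       change_summary = change_summary,
       mcnemar_participants = mcnemar_participants)
}
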