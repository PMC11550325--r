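hand_records <- function() {
  # 2 groups x 2 annotators x 2 images, values chosen for easy hand arithmetic
  rows <- expand.grid(annotator_id = c("s1", "s2", "e1", "e2"),
                      image_id = c("i1", "i2"), round = c("PRE", "POST"),
                      stringsAsFactors = FALSE)
  rows$group <- ifelse(rows$annotator_id %in% c("s1", "s2"), "STUDENT", "EXPERT")
  rows$dice <- c(0.50, 0.60, 0.70, 0.80,  0.55, 0.65, 0.75, 0.85,   # PRE
                 0.70, 0.80, 0.75, 0.85,  0.75, 0.85, 0.80, 0.90)   # POST
  rows$fp_frac <- ifelse(rows$round == "PRE", 0.30, 0.20)
  rows$fn_frac <- ifelse(rows$round == "PRE", 0.20, 0.10)
  rows$centroid_hit <- TRUE
  rows$centroid_hit[rows$round == "PRE" & rows$annotator_id == "s1"] <- FALSE
  rows[, c("annotator_id", "group", "image_id", "round", "dice",
           "fp_frac", "fn_frac", "centroid_hit")]
}

hand_changes <- function() {
  ch <- expand.grid(annotator_id = c("s1", "s2", "e1", "e2"),
                    image_id = c("i1", "i2"), stringsAsFactors = FALSE)
  ch$annotation_changed <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  ch$dice_outcome <- ifelse(ch$annotation_changed, "IMPROVED", "UNCHANGED")
  ch$group <- ifelse(ch$annotator_id %in% c("s1", "s2"), "STUDENT", "EXPERT")
  ch
}

test_that("summary tables match hand arithmetic on a tiny study", {
  tabs <- summarize_study(hand_records(), hand_changes())
  t2 <- tabs$table2
  expect_equal(t2$group, c("OVERALL", "STUDENT", "EXPERT"))
  stu_pre <- c(0.50, 0.60, 0.55, 0.65)
  stu_post <- c(0.70, 0.80, 0.75, 0.85)
  i <- t2$group == "STUDENT"
  expect_equal(t2$pre_mean[i], 100 * mean(stu_pre))
  expect_equal(t2$pre_sd[i], 100 * sd(stu_pre))      # sample (n-1) SD
  expect_equal(t2$difference[i], 100 * (mean(stu_post) - mean(stu_pre)))
  expect_equal(t2$p_value[i],
               wilcoxon_signed_rank(stu_pre, stu_post)$p_value)

  t1 <- tabs$table1
  expect_equal(t1$pre_hits[t1$group == "STUDENT"], 2)
  expect_equal(t1$post_hits[t1$group == "STUDENT"], 4)
  expect_equal(t1$pre_pct[t1$group == "OVERALL"], 100 * 6 / 8)
  expect_equal(t1$p_value[t1$group == "STUDENT"],
               fisher_exact_2x2(c(2, 2, 4, 0))$p_value)
  expect_true(is.na(t1$p_value[t1$group == "EXPERT"]))  # no change, all hit

  t3 <- tabs$table3
  o <- t3$group == "OVERALL"
  expect_equal(t3$fp_pre_mean[o], 30)
  expect_equal(t3$fp_post_mean[o], 20)
  expect_equal(t3$fp_change_mean[o], -10)
  expect_equal(t3$fn_change_mean[o], -10)
  expect_equal(t3$fp_change_sd[o], t3$fp_post_sd[o] - t3$fp_pre_sd[o])

  cs <- tabs$change_summary
  expect_equal(cs$changed[cs$group == "OVERALL"], 6)
  expect_equal(cs$changed_pct[cs$group == "EXPERT"], 50)
  expect_equal(cs$improved_pct[cs$group == "STUDENT"], 100)

  mp <- tabs$mcnemar_participants
  expect_equal(mp$pre_all_hit[mp$group == "OVERALL"], 3)  # s1 missed one
  expect_equal(mp$post_all_hit[mp$group == "OVERALL"], 4)
  expect_equal(mp$p_value[mp$group == "OVERALL"], mcnemar_exact(0, 1)$p_value)
})

test_that("identical pre and post records give all-zero differences", {
  rec <- hand_records()
  rec$dice[rec$round == "POST"] <- rec$dice[rec$round == "PRE"]
  rec$fp_frac <- 0.25; rec$fn_frac <- 0.25
  rec$centroid_hit <- TRUE
  ch <- hand_changes()
  ch$annotation_changed <- FALSE
  ch$dice_outcome <- "UNCHANGED"
  tabs <- summarize_study(rec, ch)
  expect_true(all(tabs$table2$difference == 0))
  expect_true(all(tabs$table2$p_value == 1))
  expect_true(all(tabs$table3$fp_change_mean == 0))
  expect_true(all(tabs$change_summary$changed == 0))
})

test_that("the synthetic default design yields 5-row tables", {
  ds <- generate_study(small_study_config(seed = 3))
  ev <- evaluate_dataset(ds)
  tabs <- summarize_study(ev$metrics, ev$changes)
  for (nm in c("table1", "table2", "table3", "change_summary",
               "mcnemar_participants"))
    expect_equal(nrow(tabs[[nm]]), 5)
  expect_equal(tabs$table2$group,
               c("OVERALL", "STUDENT", "JUNIOR", "INTERMEDIATE", "EXPERT"))
})

test_that("records without a PRE/POST partner are excluded with a message", {
  rec <- hand_records()
  rec <- rec[!(rec$annotator_id == "e2" & rec$image_id == "i2" &
                 rec$round == "POST"), ]
  ch <- hand_changes()
  ch <- ch[!(ch$annotator_id == "e2" & ch$image_id == "i2"), ]
  expect_message(tabs <- summarize_study(rec, ch), "excluded 1")
  expect_equal(tabs$table2$n[tabs$table2$group == "OVERALL"], 7)
})
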