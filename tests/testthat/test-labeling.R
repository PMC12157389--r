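# Conditioning-variable construction: clutch-unique mutant codes, the
# shared/held-out control split, and the stratified train/validation split.

make_labels <- function(n_ctrl = 10L, clutches = c("c1", "c2"),
                        mutants = c("mutA", "mutB"), ages = "3dpf") {
  rows <- list()
  for (i in seq_along(clutches)) {
    for (ag in ages) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s.ctrl.%s.%02d", clutches[i], ag, seq_len(n_ctrl)),
        genotype = "control", clutch = clutches[i], age = ag,
        control_flag = TRUE, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s.%s.%s.%02d", clutches[i], mutants[i], ag, 1:6),
        genotype = mutants[i], clutch = clutches[i], age = ag,
        control_flag = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("two clutches with one mutant each yield the expected code structure", {
  lab <- make_labels()
  coded <- build_condition_codes(lab, control_split_fraction = 0.5, seed = 1)
  codes <- unique(coded$genotype_code)
  expect_length(codes, 5) # 2 mutant-unique + 1 shared control + 2 held-out
  expect_length(grep("^mut", codes), 2)
  expect_length(grep("^ctrl", codes), 1)
  expect_length(grep("^hoCtrl", codes), 2)
  # half of each clutch's controls are held out
  for (cl in c("c1", "c2")) {
    expect_identical(sum(coded$heldout_control[coded$clutch == cl]), 5L)
  }
  # held-out codes are clutch-unique; shared code spans both clutches
  ho <- coded[coded$heldout_control, ]
  expect_identical(length(unique(paste(ho$genotype_code, ho$clutch))),
                   length(unique(ho$genotype_code)))
  sh <- coded[coded$control_flag & !coded$heldout_control, ]
  expect_identical(length(unique(sh$genotype_code)), 1L)
  expect_setequal(unique(sh$clutch), c("c1", "c2"))
})

test_that("the same genotype in two clutches gets two different codes", {
  lab <- make_labels(mutants = c("mutA", "mutA"))
  coded <- build_condition_codes(lab, seed = 1)
  mcodes <- unique(coded$genotype_code[!coded$control_flag])
  expect_length(mcodes, 2)
})

test_that("fraction 0 shares all controls; clutches without controls are rejected", {
  lab <- make_labels()
  coded <- build_condition_codes(lab, control_split_fraction = 0, seed = 1)
  expect_false(any(coded$heldout_control))
  expect_length(grep("^hoCtrl", unique(coded$genotype_code)), 0)
  lab2 <- lab[!(lab$control_flag & lab$clutch == "c2"), ]
  expect_error(build_condition_codes(lab2), "no controls")
})

test_that("codes are seed-stable and only the control split varies with the seed", {
  lab <- make_labels(ages = c("3dpf", "5dpf"))
  a <- build_condition_codes(lab, seed = 1)
  b <- build_condition_codes(lab, seed = 1)
  expect_identical(a$genotype_code, b$genotype_code)
  c2 <- build_condition_codes(lab, seed = 2)
  mut <- !lab$control_flag
  expect_identical(a$genotype_code[mut], c2$genotype_code[mut])
  expect_false(identical(a$heldout_control, c2$heldout_control))
  # shared control codes are per age group
  sh <- a[a$control_flag & !a$heldout_control, ]
  expect_identical(sort(unique(sh$genotype_code)),
                   sort(unique(sprintf("ctrl|%s", sh$age))))
})

test_that("the code lookup table inverts the relabeling", {
  lab <- make_labels(ages = c("3dpf", "5dpf"))
  coded <- build_condition_codes(lab, seed = 3)
  lk <- attr(coded, "lookup")
  expect_true(all(c("genotype_code", "genotype", "clutch", "age",
                    "heldout_control") %in% names(lk)))
  for (i in sample(nrow(coded), 20)) {
    row <- lk[lk$genotype_code == coded$genotype_code[i], ]
    expect_identical(unique(row$genotype), coded$genotype[i])
    expect_identical(unique(row$age), coded$age[i])
    if (!grepl("^ctrl", coded$genotype_code[i])) {
      expect_identical(unique(row$clutch), coded$clutch[i])
    }
  }
})

test_that("train/validation split is stratified, disjoint and reproducible", {
  lab <- make_labels(n_ctrl = 40L, mutants = c("mutA", "mutB"))
  coded <- build_condition_codes(lab, seed = 1)
  expect_identical(nrow(coded), 92L)
  sp <- suppressWarnings(split_train_val(coded, 0.8, seed = 1))
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), coded$sample_id)
  # per-stratum proportions
  for (cd in unique(coded$genotype_code)) {
    ids <- coded$sample_id[coded$genotype_code == cd]
    expect_equal(sum(sp$train %in% ids), max(1, round(0.8 * length(ids))))
  }
  sp2 <- suppressWarnings(split_train_val(coded, 0.8, seed = 1))
  expect_identical(sp, sp2)
  expect_error(split_train_val(coded, 1.2), "fraction")
})

test_that("singleton condition cells go to train with a warning", {
  lab <- make_labels()
  lab <- rbind(lab, data.frame(sample_id = "c1.solo.3dpf.01", genotype = "solo",
                               clutch = "c1", age = "3dpf", control_flag = FALSE))
  coded <- build_condition_codes(lab, seed = 1)
  expect_warning(sp <- split_train_val(coded, 0.8, seed = 1), "singleton")
  expect_true("c1.solo.3dpf.01" %in% sp$train)
})
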