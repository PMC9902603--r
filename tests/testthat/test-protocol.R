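# Splitting protocol and evaluation metrics: exact split arithmetic on a
# full-scale label composition, cell-level leakage, metric identities, and
# the repeated-trial report.

test_that("full-scale split arithmetic: 2144 -> 654/1490 -> +221 -> 400/1275 -> 693", {
  # wild-type-like composition, type C enriched enough for balancing
  ds <- stub_dataset(c(A = 1300, B = 641, C = 203))
  expect_length(ds, 2144)
  spec <- split_spec(test_size = 654, test_unit = "image",
                     validation_size = 400, training_size = 1275,
                     n_per_label_train = 231)
  sp <- split_dataset(ds, spec, seed = 1)
  expect_length(sp$test, 654)
  expect_length(sp$pool, 1490)
  extra <- stub_dataset(c(C = 221), prefix = "extra")
  pool <- augment_pool(sp$pool, extra)
  expect_length(pool, 1711)
  labs <- vapply(pool, `[[`, "", "label")
  expect_equal(sum(labs == "C"), sum(vapply(sp$pool, `[[`, "", "label") == "C") + 221)
  expect_equal(sum(vapply(pool, function(im) isTRUE(im$augmented), TRUE)), 221)
  # validation and training are both sampled: 400 + 1,275 of the 1,711
  vt <- select_validation_and_training(pool, 400, training_size = 1275,
                                       seed = 2)
  expect_length(vt$validation, 400)
  expect_length(vt$training, 1275)
  expect_length(intersect(vapply(vt$validation, `[[`, "", "uid"),
                          vapply(vt$training, `[[`, "", "uid")), 0)
  bal <- balanced_subset(vt$training, 231, seed = 3)
  expect_length(bal, 693)
  expect_equal(as.vector(table(vapply(bal, `[[`, "", "label"))),
               c(231, 231, 231))
})

test_that("cell-level test selection never splits a cell", {
  ds <- stub_dataset(c(A = 300, B = 150, C = 50), n_cells = 36)
  spec <- split_spec(test_size = 150, test_unit = "cell")
  sp <- split_dataset(ds, spec, seed = 4)
  test_cells <- unique(vapply(sp$test, `[[`, "", "cell_id"))
  pool_cells <- unique(vapply(sp$pool, `[[`, "", "cell_id"))
  expect_length(intersect(test_cells, pool_cells), 0)
  expect_gte(length(sp$test), 150)  # whole cells: reaches the target
  expect_length(c(sp$test, sp$pool), 500)
})

test_that("splits are seeded-deterministic and validated", {
  ds <- stub_dataset(c(A = 40, B = 40, C = 40))
  spec <- split_spec(test_size = 30, test_unit = "image")
  s1 <- split_dataset(ds, spec, seed = 9)
  s2 <- split_dataset(ds, spec, seed = 9)
  expect_identical(vapply(s1$test, `[[`, "", "uid"),
                   vapply(s2$test, `[[`, "", "uid"))
  expect_error(split_dataset(ds, split_spec(test_size = 500)), "exceeds")
  expect_error(select_validation_and_training(ds, 120), "below pool size")
  expect_error(balanced_subset(ds, 41), "type A")
  expect_identical(augment_pool(ds, list()), ds)
})

test_that("concordance, distribution and confusion obey their identities", {
  expect_equal(concordance_rate(c("A", "A", "B"), c("A", "B", "B")),
               200 / 3)
  expect_equal(concordance_rate(rep("A", 5), rep("A", 5)), 100)
  expect_equal(concordance_rate(rep("A", 4), rep("C", 4)), 0)
  expect_error(concordance_rate(c("A", "B"), c("A")), "length")
  expect_error(concordance_rate(character(0), character(0)), "empty")

  expect_equal(unname(type_distribution(c("A", "A", "B", "C"))), c(50, 25, 25))
  expect_equal(unname(type_distribution(rep("A", 7))), c(100, 0, 0))
  expect_equal(sum(type_distribution(c("A", "B", "B", "C", "C", "C"))), 100)
  # counts chosen to reproduce a 63.8 / 31.3 / 4.9 split
  d <- type_distribution(rep(c("A", "B", "C"), c(417, 205, 32)))
  expect_equal(round(unname(d), 1), c(63.8, 31.3, 4.9))
  expect_error(type_distribution(character(0)), "no labels")

  set.seed(2)
  ea <- sample(c("A", "B", "C"), 120, replace = TRUE)
  pa <- sample(c("A", "B", "C"), 120, replace = TRUE)
  cm <- confusion_matrix(ea, pa)
  expect_equal(rowSums(cm), c(A = sum(ea == "A"), B = sum(ea == "B"),
                              C = sum(ea == "C")))
  expect_equal(100 * sum(diag(cm)) / sum(cm), concordance_rate(ea, pa))
})

test_that("run_protocol executes n_selections x n_repeats trials and averages them", {
  ds <- small_dataset()
  spec <- split_spec(test_size = 15, test_unit = "image",
                     validation_size = 9, n_per_label_train = 8,
                     n_selections = 2, n_repeats = 2)
  mc <- list(backbone = small_backbone(), preprocess = small_pp(),
             hyper = head_hyperparams(epochs = 5))
  rep1 <- run_protocol(ds, spec, mc, base_seed = 11)
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(rep1$n_trials, 4)
  expect_length(rep1$per_trial, 4)
  # averaging identities
  expect_equal(rep1$concordance,
               mean(vapply(rep1$per_trial, `[[`, numeric(1), "concordance")))
  expect_equal(unname(rep1$distribution$PA),
               unname(colMeans(do.call(rbind,
                 lapply(rep1$per_trial, function(t) t$distribution$PA)))))
  # per-trial confusion trace identity
  for (t in rep1$per_trial) {
    expect_equal(100 * sum(diag(t$confusion)) / sum(t$confusion),
                 t$concordance)
  }
  expect_true(all(abs(vapply(rep1$per_trial,
                             function(t) sum(t$distribution$PA),
                             numeric(1)) - 100) < 1e-9))
  # seeded determinism of the whole report
  rep2 <- run_protocol(ds, spec, mc, base_seed = 11)
  expect_equal(rep1$concordance, rep2$concordance)
  expect_identical(rep1$confusion, rep2$confusion)
  # a single trial is its own average
  spec1 <- split_spec(test_size = 15, test_unit = "image",
                      validation_size = 9, n_per_label_train = 8,
                      n_selections = 1, n_repeats = 1)
  r1 <- run_protocol(ds, spec1, mc, base_seed = 3)
  expect_equal(r1$n_trials, 1)
  expect_equal(r1$concordance, r1$per_trial[[1]]$concordance)
})

test_that("no image leaks between test, validation and training in a trial", {
  ds <- small_dataset()
  spec <- split_spec(test_size = 15, test_unit = "cell",
                     validation_size = 9, n_per_label_train = 5,
                     n_selections = 1, n_repeats = 1)
  sp <- split_dataset(ds, spec, seed = 5)
  vt <- select_validation_and_training(sp$pool, 9, seed = 6)
  bal <- balanced_subset(vt$training, 5, seed = 7)
  ids <- list(test = vapply(sp$test, `[[`, "", "uid"),
              val = vapply(vt$validation, `[[`, "", "uid"),
              bal = vapply(bal, `[[`, "", "uid"))
  expect_length(intersect(ids$test, ids$val), 0)
  expect_length(intersect(ids$test, ids$bal), 0)
  expect_length(intersect(ids$val, ids$bal), 0)
  test_cells <- vapply(sp$test, `[[`, "", "cell_id")
  pool_cells <- vapply(sp$pool, `[[`, "", "cell_id")
  expect_length(intersect(unique(test_cells), unique(pool_cells)), 0)
})

test_that("training_size_sweep returns one averaged concordance per size", {
  ds <- small_dataset()
  spec <- split_spec(test_size = 15, test_unit = "image",
                     validation_size = 9, n_selections = 1, n_repeats = 1)
  mc <- list(backbone = small_backbone(), preprocess = small_pp(),
             hyper = head_hyperparams(epochs = 5))
  sw <- training_size_sweep(ds, spec, sizes = c(2, 8, 8), mc, seed = 13)
  expect_equal(sw$n_per_label, c(2L, 8L, 8L))
  expect_true(all(sw$concordance >= 0 & sw$concordance <= 100))
  # duplicate sizes are evaluated under independent derived seeds
  reports <- attr(sw, "reports")
  expect_length(reports, 3)
  expect_false(identical(reports[[2]]$per_trial[[1]]$seed,
                         reports[[3]]$per_trial[[1]]$seed))
})
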