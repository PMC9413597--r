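test_that("decode_mask thresholds at 0.5 with an at-least-one fallback", {
  expect_equal(decode_mask(c(0.9, 0.1, 0.6)), c(TRUE, FALSE, TRUE))
  expect_equal(decode_mask(c(0.1, 0.2, 0.3)), c(FALSE, FALSE, TRUE))
  expect_equal(decode_mask(c(0.5, 0.5, 0.5)), c(TRUE, FALSE, FALSE))
})

test_that("selection fitness matches direct evaluation of the formula", {
  expect_equal(round(selection_fitness(0.9558, 12, 44), 4), 0.0465)
  expect_equal(selection_fitness(0.9558, 12, 44),
               0.99 * (1 - 0.9558) + 0.01 * 12 / 44, tolerance = 1e-12)
  expect_equal(selection_fitness(1, 1, 44), 0.01 / 44, tolerance = 1e-9)
  expect_equal(selection_fitness(0.9317, 44, 44), 0.077617,
               tolerance = 1e-9)
  expect_error(selection_fitness(0.9, 45, 44), "feasel")
  expect_error(selection_fitness(1.2, 3, 44), "acc")
  expect_error(fitness_config(alpha = 0.99, beta = 0.02), "beta")
})

test_that("fitness is decreasing in accuracy and increasing in subset size", {
  accs <- seq(0, 1, by = 0.1)
  f_acc <- vapply(accs, selection_fitness, numeric(1), feasel = 10,
                  numfea = 44)
  expect_true(all(diff(f_acc) < 0))
  sizes <- 1:44
  f_size <- vapply(sizes, function(k)
    selection_fitness(0.9, k, 44), numeric(1))
  expect_true(all(diff(f_size) > 0))
})

test_that("cross-validated accuracy separates signal from noise", {
  mt <- make_table(table_spec(n_per_class = 60, k_informative = 1,
                              k_redundant = 0, k_noise = 9,
                              effect_size = 10, seed = 11))
  cfg <- lda_fitness()
  informative <- c(TRUE, rep(FALSE, 9))
  noise_only <- c(FALSE, TRUE, rep(FALSE, 8))
  acc_inf <- cv_accuracy(mt$table, informative, cfg)
  acc_noise <- cv_accuracy(mt$table, noise_only, cfg)
  expect_gte(acc_inf, 0.99)
  expect_lt(acc_noise, acc_inf)
  # chance band under seeded label permutation
  perm <- mt$table
  perm$label <- withr::with_seed(99, sample(perm$label))
  acc_perm <- cv_accuracy(perm, rep(TRUE, 10), cfg)
  expect_gte(acc_perm, 0.35)
  expect_lte(acc_perm, 0.65)
  # deterministic under fixed seeds
  expect_identical(cv_accuracy(mt$table, informative, cfg),
                   cv_accuracy(mt$table, informative, cfg))
  expect_error(cv_accuracy(mt$table[c(1:3, 61:63), ], informative, cfg),
               "fewer samples")
})

test_that("the default gradient-boosted classifier plugs into the fitness", {
  mt <- make_table(table_spec(n_per_class = 40, k_informative = 2,
                              k_redundant = 0, k_noise = 4,
                              effect_size = 4, seed = 3))
  acc <- cv_accuracy(mt$table, rep(TRUE, 6),
                     fitness_config(classifier = "xgboost", cv_seed = 2))
  expect_gte(acc, 0.9)
})

test_that("stratified 6:4 split reproduces the per-class test sizes", {
  tab <- make_table(table_spec(n_per_class = 5, k_informative = 2,
                               k_redundant = 0, k_noise = 2, seed = 1))$table
  # rebuild at the study's class sizes: 1197 eating / 779 drinking
  big <- tab[c(rep(1:5, length.out = 1197), rep(6:10, length.out = 779)), ]
  big$label <- c(rep("eating", 1197), rep("drinking", 779))
  big <- structure(big, feature_names = attr(tab, "feature_names"),
                   class = class(tab))
  sp <- split_and_normalize(big, train_frac = 0.6, seed = 4)
  expect_equal(nrow(sp$test), 791L)
  expect_equal(sum(sp$test$label == "eating"), 479L)
  expect_equal(sum(sp$test$label == "drinking"), 312L)
  expect_equal(nrow(sp$train), 1976L - 791L)
  # a different seed changes membership but not sizes
  sp2 <- split_and_normalize(big, train_frac = 0.6, seed = 5)
  expect_equal(nrow(sp2$test), nrow(sp$test))
  expect_false(identical(sp2$test[[1]], sp$test[[1]]))
})

test_that("min-max scaling is fit on train only and maps train to [0, 1]", {
  mt <- make_table(table_spec(n_per_class = 50, seed = 8))
  sp <- split_and_normalize(mt$table, 0.6, seed = 2)
  X <- as.matrix(sp$train[, attr(sp$train, "feature_names")])
  expect_equal(unname(apply(X, 2, min)), rep(0, ncol(X)))
  expect_equal(unname(apply(X, 2, max)), rep(1, ncol(X)))
  # test rows may exceed [0, 1]; the scaler must come from train
  Xt <- as.matrix(sp$test[, attr(sp$test, "feature_names")])
  expect_true(any(Xt < 0 | Xt > 1))
  # constant training feature scaled to 0 with a warning
  ct <- mt$table
  ct$inf_01 <- 1
  expect_warning(spc <- split_and_normalize(ct, 0.6, seed = 2), "constant")
  expect_equal(unique(spc$train$inf_01), 0)
})

test_that("select_features returns a valid, reproducible selection", {
  mt <- make_table(table_spec(n_per_class = 60, k_informative = 3,
                              k_redundant = 2, k_noise = 7,
                              effect_size = 2, seed = 21))
  oc <- optimizer_config(pop_size = 10, max_iter = 12, seed = 2)
  sel <- select_features(mt$table, oc, lda_fitness())
  expect_s3_class(sel, "selection_result")
  expect_gte(sel$feasel, 1)             # never an empty mask
  expect_equal(sel$feasel, sum(sel$mask))
  expect_equal(sel$fitness,
               0.99 * (1 - sel$cv_accuracy) + 0.01 * sel$feasel / 12,
               tolerance = 1e-12)
  expect_equal(sel$selected_features,
               attr(mt$table, "feature_names")[sel$mask])
  sel2 <- select_features(mt$table, oc, lda_fitness())
  expect_identical(sel$mask, sel2$mask)
  expect_identical(sel$curve, sel2$curve)
})

test_that("a single-feature table is forced to the full mask", {
  mt <- make_table(table_spec(n_per_class = 30, k_informative = 1,
                              k_redundant = 0, k_noise = 0,
                              effect_size = 3, seed = 2))
  sel <- select_features(mt$table,
                         optimizer_config(pop_size = 4, max_iter = 3,
                                          seed = 1),
                         lda_fitness())
  expect_equal(sel$mask, TRUE)
  expect_equal(sel$fitness, 0.99 * (1 - sel$cv_accuracy) + 0.01,
               tolerance = 1e-12)
})

test_that("IWOA selection fitness is no worse than WOA in the median", {
  mt <- make_table(recovery_table_spec())
  fits <- sapply(1:6, function(s) {
    c(iwoa = select_features(mt$table,
                             optimizer_config(pop_size = 10, max_iter = 15,
                                              variant = "iwoa", seed = s),
                             lda_fitness())$fitness,
      woa = select_features(mt$table,
                            optimizer_config(pop_size = 10, max_iter = 15,
                                             variant = "woa", seed = s),
                            lda_fitness())$fitness)
  })
  expect_lte(median(fits["iwoa", ]), median(fits["woa", ]))
})
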