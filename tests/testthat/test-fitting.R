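make_study <- function(monomers, seed, noise = 0, n_or = 2) {
  spec <- synthetic_spec(monomers = monomers, n_orientations = n_or,
                         noise_sd = noise, seed = seed)
  generate_synthetic_study(spec)
}

test_that("the multi-target loss combines component and total MSEs", {
  study <- make_study(c("methane", "formaldehyde"), seed = 3, n_or = 1)
  ds <- study$train
  # independent computation from predictions
  pred <- predict_sapt(study$truth, ds)
  ref <- reference_records(ds)
  pm <- t(sapply(pred, unlist)); rm_ <- t(sapply(ref, unlist))
  mse <- colMeans((pm - rm_)^2)
  for (g in c(0, 0.4, 1)) {
    want <- (1 - g) * mse[["total"]] + g * sum(mse[1:4])
    expect_equal(sapt_loss(study$truth, ds, gamma = g), want, tolerance = 1e-12)
  }
  # perfect parameters give (numerically) zero loss
  expect_lt(sapt_loss(study$truth, ds, 0.4), 1e-18)
  # a perturbed parameter set gives a positive loss
  worse <- study$truth
  worse$K_exch <- worse$K_exch * 1.3
  expect_gt(sapt_loss(worse, ds, 0.4), 0)
})

test_that("the loss is invariant to record order", {
  study <- make_study(c("methane", "methanol", "hydrogen_cyanide"), seed = 5,
                      noise = 0.3, n_or = 1)
  ds <- sapt_dataset(c(study$train$records, study$test$records))
  p <- study$truth
  l1 <- sapt_loss(p, ds, 0.4)
  set.seed(1)
  l2 <- sapt_loss(p, sapt_dataset(sample(ds$records)), 0.4)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  study <- make_study(c("methane", "methanol"), seed = 5, noise = 0.3, n_or = 1)
  ds <- sapt_dataset(c(study$train$records, study$test$records))
  sp <- dataset_species(ds)
  des <- saptfit:::build_design(ds, sp)
  ns <- length(sp)
  set.seed(8)
  theta <- log(runif(4 * ns, 0.5, 3))
  for (g in c(0.4, 1)) {
    ga <- saptfit:::design_loss_grad(des, theta, g)
    fn <- function(th) {
      k <- exp(th)
      p <- saptfit:::eval_design(des, k[1:ns], k[ns + 1:ns],
                                 k[2 * ns + 1:ns], k[3 * ns + 1:ns])
      saptfit:::loss_from_predictions(p, des$ref, g)
    }
    gn <- sapply(seq_along(theta), function(p) {
      h <- 1e-6; tp <- theta; tm <- theta
      tp[p] <- tp[p] + h; tm[p] <- tm[p] - h
      (fn(tp) - fn(tm)) / (2 * h)
    })
    expect_equal(ga, gn, tolerance = 1e-5)
  }
})

test_that("noise-free fits recover the generating parameters", {
  study <- make_study(c("methane", "methanol", "formaldehyde"), seed = 11,
                      n_or = 3)
  fit <- fit_parameters(study$train, fit_config())
  expect_true(fit$converged)
  expect_lt(fit$loss, 1e-10)
  sp <- fit$species
  for (cc in c("K_elst", "K_exch", "K_indu", "K_disp")) {
    expect_lt(max(abs(param_lookup(fit$params, sp, cc) /
                        param_lookup(study$truth, sp, cc) - 1)), 1e-3)
  }
  # loss trace mirrors the convergence curve: non-increasing
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("species absent from training stay blank in the result", {
  lib <- monomer_library()["methane"]
  spec <- synthetic_spec(monomers = "methane", n_orientations = 2, seed = 2)
  dimers <- sample_dimer_configurations(lib, spec, which = "homo")
  props <- lapply(lib, synth_atomic_properties, seed = 2)
  train <- generate_reference_dataset(dimers, props,
                                      ground_truth_parameters(2), seed = 2)
  fit <- fit_parameters(train, fit_config())
  expect_setequal(fit$species, c("C4", "HC"))
  expect_setequal(fit$missing_species, setdiff(species_vocabulary(),
                                               c("C4", "HC")))
  blank <- fit$params[fit$params$species == "O2", ]
  expect_true(all(is.na(unlist(blank[, -1]))))
})

test_that("gamma changes the optimum but not the trace monotonicity", {
  study <- make_study(c("methane", "methanol"), seed = 13, noise = 0.4, n_or = 2)
  f0 <- fit_parameters(study$train, fit_config(gamma = 0, max_iter = 300))
  f1 <- fit_parameters(study$train, fit_config(gamma = 1, max_iter = 300))
  expect_true(all(diff(f0$trace) <= 0))
  expect_true(all(diff(f1$trace) <= 0))
  expect_false(isTRUE(all.equal(f0$params$K_exch, f1$params$K_exch)))
})

test_that("prediction demands full species coverage", {
  study <- make_study(c("methane", "methanethiol"), seed = 4, n_or = 1)
  fit_methane <- fit_parameters(
    sapt_dataset(study$train$records[1]), fit_config(max_iter = 50))
  # methane-only parameters cannot predict a thiol dimer
  expect_error(predict_sapt(fit_methane$params,
                            sapt_dataset(study$train$records[2])),
               "S2|HS")
  # but homodimer-trained parameters cover the heterodimers
  fit_all <- fit_parameters(study$train, fit_config(max_iter = 300))
  pred <- predict_sapt(fit_all$params, study$test)
  expect_length(pred, length(study$test$records))
  expect_s3_class(pred[[1]], "sapt_record")
})

test_that("empty datasets and missing references are rejected", {
  expect_error(sapt_dataset(list()), "empty")
  study <- make_study(c("methane", "formaldehyde"), seed = 3, n_or = 1)
  bare <- sapt_dataset(lapply(study$train$records, function(r) {
    r$ref <- NULL; r
  }))
  expect_error(fit_parameters(bare), "reference")
  expect_length(predict_sapt(study$truth, structure(list(records = list()),
                                                    class = "sapt_dataset")), 0L)
})

test_that("parameter tables round-trip through the blank-cell CSV layout", {
  p <- ground_truth_parameters(5)
  p$K_elst[p$species %in% c("N2", "Br")] <- NA
  tmp <- tempfile(fileext = ".csv")
  write_parameters(p, tmp)
  q <- read_parameters(tmp)
  expect_equal(q$K_exch, p$K_exch, tolerance = 1e-9)
  expect_true(all(is.na(q$K_elst[q$species %in% c("N2", "Br")])))
  expect_equal(q$species, species_vocabulary())
})
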