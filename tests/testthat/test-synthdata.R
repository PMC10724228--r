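test_that("noiseless identity datasets preserve the latent order exactly", {
  syn <- generate_synth(synth_config(n_polymers = 15, n_datasets = 3,
                                     transforms = c("identity", "log1p",
                                                    "power:2"),
                                     noise_sd = 0, seed = 21))
  for (ds in syn$datasets) {
    idx <- match(ds$records$abbreviation, syn$ground_truth$polymer)
    tau <- cor(ds$records$value, syn$ground_truth$latent[idx],
               method = "kendall")
    expect_equal(tau, 1)
    expect_true(all(is.finite(ds$records$value)))
    expect_true(all(ds$records$value >= 0))
  }
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_polymers = 10, n_datasets = 2, noise_sd = 0.1,
                      seed = 5)
  a <- generate_synth(cfg)
  b <- generate_synth(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(lapply(a$datasets, `[[`, "records"),
                   lapply(b$datasets, `[[`, "records"))
})

test_that("overlapping polymers share fingerprints across datasets", {
  syn <- generate_synth(synth_config(n_polymers = 10, n_datasets = 2,
                                     overlap = 3, noise_sd = 0.1, seed = 9))
  a <- syn$datasets[[1]]; b <- syn$datasets[[2]]
  shared <- intersect(a$records$abbreviation, b$records$abbreviation)
  expect_equal(length(shared), 3L)
  fa <- attr(a, "fingerprints")[match(shared, a$records$abbreviation), ]
  fb <- attr(b, "fingerprints")[match(shared, b$records$abbreviation), ]
  expect_equal(fa, fb)
  # but observed values differ (independent noise per dataset)
  va <- a$records$value[match(shared, a$records$abbreviation)]
  vb <- b$records$value[match(shared, b$records$abbreviation)]
  expect_false(isTRUE(all.equal(va, vb)))
})

test_that("invalid configurations are refused", {
  expect_error(synth_config(transforms = "exp!"), "unknown transform")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(synth_config(n_polymers = 5, overlap = 5), "overlap")
})

test_that("the packaged datasets have the published shapes and overlaps", {
  fx <- fixtures()
  expect_equal(vapply(fx, function(d) nrow(d$records), integer(1)),
               c(literature = 24L, exp1 = 7L, exp2 = 8L))
  abbr <- unlist(lapply(fx, function(d) d$records$abbreviation))
  dup <- names(which(table(abbr) == 2))
  expect_setequal(dup, c("PS", "PC"))
  # the shared polymers are the same structures in both datasets
  lit <- fx$literature$records; e2 <- fx$exp2$records
  expect_equal(lit$smiles[lit$abbreviation == "PS"],
               e2$smiles[e2$abbreviation == "PS"])
  expect_equal(lit$smiles[lit$abbreviation == "PC"],
               e2$smiles[e2$abbreviation == "PC"])
  expect_equal(fx$exp1$records$value[fx$exp1$records$abbreviation == "PIPA"],
               0.0002196)
})

test_that("fixtures mode draws real repeat units through the chemistry path", {
  syn <- generate_synth(synth_config(n_polymers = 8, n_datasets = 2,
                                     noise_sd = 0, seed = 2,
                                     smiles_source = "fixtures"))
  for (ds in syn$datasets) {
    expect_true(all(smiles_parses(ds$records$smiles)))
    fp <- attr(ds, "fingerprints")
    expect_equal(dim(fp), c(8L, 300L))
    refp <- fingerprint_polymers(ds$records$smiles)
    expect_equal(unname(fp), unname(refp))
  }
})
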