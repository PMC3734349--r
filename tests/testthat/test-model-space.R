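test_that("the neurofeedback pair is a mirrored, structurally identical pair", {
  pair <- attention_pair()
  skL <- validate_model(pair$aL)
  skR <- validate_model(pair$aR)
  expect_identical(skL$A_mask, skR$A_mask)

  # M_aL: input to the right SPL only, modulation on the right hemisphere
  expect_identical(which(skL$C_mask[, 1]),
                   c(SPL_R = match("SPL_R", skL$regions)))
  expect_true(skL$B_mask["VC_R", "SPL_R", 1])
  expect_true(skL$B_mask["SPL_R", "VC_R", 1])
  expect_false(any(skL$B_mask[c("VC_L", "SPL_L"), , 1]))

  # hemisphere swap is an involution mapping M_aL onto M_aR
  sw <- swap_hemispheres(pair$aL)
  expect_identical(sw$hemisphere, pair$aR$hemisphere)
  expect_identical(validate_model(sw)$B_mask, skR$B_mask)
  expect_identical(swap_hemispheres(sw)$hemisphere, pair$aL$hemisphere)
})

test_that("the comparison family has the 3 x 4 grid structure", {
  fam <- model_family()
  expect_length(fam, 12)

  keys <- vapply(fam, function(m) paste(m$input_target, m$modulation),
                 character(1))
  expect_length(unique(keys), 12)

  # model 1 is the neurofeedback architecture
  expect_identical(fam[[1]]$input_target, "SPL")
  expect_identical(fam[[1]]$modulation, "both")
  expect_identical(validate_model(fam[[1]])$B_mask,
                   validate_model(attention_pair()$aL)$B_mask)

  # models 5-8 receive direct input into VC; 9-12 into both
  for (i in 5:8) expect_identical(fam[[i]]$input_target, "VC")
  for (i in 9:12) expect_identical(fam[[i]]$input_target, "both")

  # model 4 (SPL input, no modulation) has an empty B matrix
  expect_false(any(validate_model(fam[[4]])$B_mask))

  # every family member validates into a 4-region skeleton
  for (m in fam) {
    sk <- validate_model(m)
    expect_s3_class(sk, "dcm_skeleton")
    expect_identical(sk$n_regions, 4L)
  }
})

test_that("modulation on a structurally absent edge is rejected", {
  bad <- model_spec("bad", "SPL", "both", "R",
                    extra_modulation = list(c("VC_L", "SPL_R")))
  expect_error(validate_model(bad), "structurally absent")
})

test_that("model specs round-trip through YAML", {
  spec <- model_family()[[7]]
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_identical(back$input_target, spec$input_target)
  expect_identical(back$modulation, spec$modulation)
  expect_identical(back$hemisphere, spec$hemisphere)
})

test_that("skeleton_to_params keeps structural zeros at exactly zero", {
  skel <- validate_model(attention_pair()$aL)
  with_fixture_seed(3, {
    th <- rnorm(length(skel$theta_names))
    params <- skeleton_to_params(skel, th)
    # interhemispheric entries stay zero whatever theta is
    off <- !skel$A_mask & row(skel$A_mask) != col(skel$A_mask)
    expect_true(all(params$A[off] == 0))
    expect_true(all(diag(params$A) < 0))
    expect_true(all(params$B[!skel$B_mask] == 0))
    expect_true(all(params$C[!skel$C_mask] == 0))
  })
})
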