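test_that("cosine similarity behaves as the standard normalized dot product", {
  v <- c(0.3, -1.2, 4)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 1)), 0.8)
  expect_error(cosine_similarity(c(0, 0), v), "zero vectors")
})

test_that("threshold calibration finds the equal-error operating point", {
  # perfectly separated scores: EER 0 at the lowest zero-error candidate
  r <- calibrate_threshold(rep(0.9, 5), rep(0.1, 5))
  expect_equal(r$eer, 0)
  expect_equal(r$threshold, 0.9)
  expect_equal(r$far, 0); expect_equal(r$frr, 0)
  # identical score distributions: EER 0.5
  s <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(calibrate_threshold(s, s)$eer, 0.5)
  # toy lists vs an exhaustive sweep oracle
  gen <- c(0.9, 0.8, 0.4); imp <- c(0.6, 0.3, 0.2)
  r <- calibrate_threshold(gen, imp)
  cand <- sort(unique(c(gen, imp)))
  far <- sapply(cand, function(t) mean(imp >= t))
  frr <- sapply(cand, function(t) mean(gen < t))
  best <- which.min(abs(far - frr))
  expect_equal(r$threshold, cand[best])
  expect_equal(r$eer, (far[best] + frr[best]) / 2)
  expect_error(calibrate_threshold(numeric(0), imp), "non-empty")
})

test_that("credential store keeps salted hashes and verifies passwords", {
  st <- credential_store()
  st <- add_credential(st, "dr.lee", "correct horse")
  expect_true(check_credential(st, "dr.lee", "correct horse"))
  expect_false(check_credential(st, "dr.lee", "wrong"))
  expect_false(check_credential(st, "nobody", "x"))
  expect_false(grepl("correct horse", paste(unlist(st), collapse = " ")))
  expect_gte(nchar(st[["dr.lee"]]$salt), 16)
})

test_that("enrollment centroids are order-invariant and thresholds are clamped", {
  pipe <- trained_pipeline(1)
  recs <- scaled_study_records(1)
  subj <- sapply(recs, `[[`, "subject_id")
  enroll_idx <- intersect(pipe$splits$train, which(subj == 1))[1:4]
  args <- list(model = pipe$model, fspec = pipe$fspec, wspec = pipe$wspec,
               decimation = pipe$decimation)
  t1 <- do.call(enroll_subject, c(list(1, recs[enroll_idx]), args))
  t2 <- do.call(enroll_subject, c(list(1, recs[rev(enroll_idx)]), args))
  expect_equal(t1$centroid, t2$centroid)
  # single-record enrollment: centroid equals that record's mean embedding
  t3 <- do.call(enroll_subject, c(list(1, recs[enroll_idx[1]]), args))
  emb <- semgid:::.embed_record(recs[[enroll_idx[1]]], pipe$model, pipe$fspec,
                                pipe$wspec, pipe$decimation)
  expect_equal(t3$centroid, emb)
  # threshold clamping to [-1, 1]
  t4 <- do.call(enroll_subject,
                c(list(1, recs[enroll_idx[1]]), args, threshold = 1.5))
  expect_equal(t4$threshold, 1)
})

test_that("genuine similarities dominate impostor similarities for every subject", {
  pipe <- trained_pipeline(1)
  recs <- scaled_study_records(1)
  vs <- verification_scores(recs[pipe$splits$train], recs[pipe$splits$test],
                            pipe$model, pipe$fspec, pipe$wspec, pipe$decimation)
  sc <- vs$scores
  for (sid in unique(sc$claimed)) {
    gen <- sc$score[sc$claimed == sid & sc$genuine]
    imp <- sc$score[sc$claimed == sid & !sc$genuine]
    expect_gt(min(gen), mean(imp))
  }
  # calibrated thresholds: held-out FAR and FRR agree with the EER
  cal <- calibrate_threshold(sc$score[sc$genuine], sc$score[!sc$genuine])
  expect_lte(cal$eer, 0.1)
  expect_lte(abs(cal$far - cal$frr), 0.05)
})

test_that("general access is the conjunction of credential and biometric factors", {
  pipe <- trained_pipeline(1)
  recs <- scaled_study_records(1)
  subj <- sapply(recs, `[[`, "subject_id")
  args <- list(model = pipe$model, fspec = pipe$fspec, wspec = pipe$wspec,
               decimation = pipe$decimation)
  enroll_idx <- intersect(pipe$splits$train, which(subj == 1))[1:6]
  vs <- verification_scores(recs[enroll_idx],
                            recs[intersect(pipe$splits$val, which(subj <= 2))],
                            pipe$model, pipe$fspec, pipe$wspec, pipe$decimation)
  cal <- calibrate_threshold(vs$scores$score[vs$scores$genuine],
                             vs$scores$score[!vs$scores$genuine])
  template <- vs$templates[["1"]]
  template$threshold <- cal$threshold
  genuine_rec <- recs[[intersect(pipe$splits$test, which(subj == 1))[1]]]
  impostor_rec <- recs[[intersect(pipe$splits$test, which(subj == 3))[1]]]
  st <- add_credential(credential_store(), "subj1", "pw1")

  run <- function(rec, pw) do.call(authenticate, c(list(
    "general", rec, template,
    credentials = list(username = "subj1", password = pw), store = st), args))
  cases <- list(
    list(d = run(genuine_rec, "pw1"), accepted = TRUE, reason = "none"),
    list(d = run(genuine_rec, "bad"), accepted = FALSE, reason = "credential"),
    list(d = run(impostor_rec, "pw1"), accepted = FALSE, reason = "biometric"),
    list(d = run(impostor_rec, "bad"), accepted = FALSE, reason = "credential"))
  for (cs in cases) {
    expect_identical(cs$d$accepted, cs$accepted)
    expect_identical(cs$d$reason, cs$reason)
  }
  # emergency mode: biometric only, no credentials needed
  d <- do.call(authenticate, c(list("emergency", genuine_rec, template), args))
  expect_true(d$accepted)
  d <- do.call(authenticate, c(list("emergency", impostor_rec, template), args))
  expect_false(d$accepted)
  expect_identical(d$reason, "biometric")
  # self-verification of an enrollment record scores near 1
  d <- do.call(verify_semg, c(list(recs[[enroll_idx[1]]], template), args))
  expect_gt(d$similarity, 0.95)
  expect_error(do.call(authenticate, c(list("general", genuine_rec, template,
                                            credentials = list(username = "ghost",
                                                               password = "x"),
                                            store = st), args)),
               "unknown username")
})

test_that("template stores round-trip through JSON", {
  tp <- structure(list(subject_id = 3L, centroid = c(0.25, -1, 2.5),
                       n_enrolled = 4L, threshold = 0.62),
                  class = "subject_template")
  path <- withr::local_tempfile(fileext = ".json")
  write_templates(list(tp), path)
  back <- read_templates(path)
  expect_length(back, 1)
  expect_equal(back[["3"]]$centroid, tp$centroid)
  expect_equal(back[["3"]]$threshold, tp$threshold)
  expect_identical(back[["3"]]$subject_id, 3L)
})
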