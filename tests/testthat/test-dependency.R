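test_that("response-table validation names offending events", {
  rt <- random_rt(4)
  expect_s3_class(validate_response_table(rt), "response_table")
  expect_error(
    validate_response_table(rt[-1, ]),
    "5 \\(not 6\\) questions.*ev001"
  )
  rt_bad <- rt
  rt_bad$correct[1] <- 2
  expect_error(validate_response_table(rt_bad), "0/1")
  expect_error(
    validate_response_table(rbind(rt, rt[1, ])),
    "duplicate"
  )
  expect_error(
    validate_response_table(rt[, -1]),
    "missing column"
  )
})

test_that("contingency tables conserve event counts", {
  rt <- random_rt(18, p = 0.7, seed = 4)
  tabs <- build_contingency_tables(rt, "p001", "neutral", "simultaneous")
  expect_equal(nrow(tabs), 6)
  expect_true(all(tabs$n11 + tabs$n10 + tabs$n01 + tabs$n00 == 18))
  expect_setequal(tabs$table_kind, c("cue_common", "target_common"))
  expect_setequal(tabs$common_category, c("location", "person", "object"))
})

test_that("D is the mean proportion of agreeing outcomes", {
  # hand-counted table: (11 both, 4 first-only, 3 second-only, 0 neither)
  tabs <- tibble::tibble(
    table_kind = "cue_common", common_category = "person",
    n11 = 11, n10 = 4, n01 = 3, n00 = 0, n = 18
  )
  expect_equal(compute_D(tabs), 11 / 18)

  q_all <- matrix(1L, 4, 6, dimnames = list(NULL, all_question_names()))
  rt <- rt_from_qmat(q_all)
  tabs_all <- build_contingency_tables(rt, "p001", "neutral", "simultaneous")
  expect_equal(compute_D(tabs_all), 1)
  expect_true(all(tabs_all$n11 == 4))
})

test_that("Di follows the product-of-marginals arithmetic", {
  # every question at marginal 1 -> Di = 1; at 0.5 -> Di = 0.5
  q1 <- matrix(1L, 4, 6, dimnames = list(NULL, all_question_names()))
  expect_equal(
    compute_Di(rt_from_qmat(q1), "p001", "neutral", "simultaneous"), 1
  )
  qh <- matrix(rep(c(0L, 1L), 12), 4, 6,
    dimnames = list(NULL, all_question_names())
  )
  expect_equal(
    compute_Di(rt_from_qmat(qh), "p001", "neutral", "simultaneous"), 0.5
  )
  # asymmetric marginals: recompute every table by hand from the marginals.
  # The cue-common person table with P_AB = 0.8, P_AC = 0.7 contributes
  # 0.56 + 0.06 = 0.62.
  set.seed(31)
  q <- matrix(rbinom(60, 1, 0.5), 10, 6,
    dimnames = list(NULL, all_question_names())
  )
  q[, "person.location"] <- c(rep(1L, 8), 0L, 0L)
  q[, "person.object"] <- c(rep(1L, 7), 0L, 0L, 0L)
  rt <- rt_from_qmat(q)
  pair_for <- function(a, kind) {
    bc <- setdiff(c("location", "person", "object"), a)
    if (kind == "cue_common") {
      paste(a, bc, sep = ".")
    } else {
      paste(bc, a, sep = ".")
    }
  }
  manual <- mean(unlist(lapply(
    c("location", "person", "object"),
    function(a) {
      lapply(c("cue_common", "target_common"), function(kind) {
        qs <- pair_for(a, kind)
        p1 <- mean(q[, qs[1]])
        p2 <- mean(q[, qs[2]])
        p1 * p2 + (1 - p1) * (1 - p2)
      })
    }
  )))
  expect_equal(0.8 * 0.7 + 0.2 * 0.3, 0.62)
  expect_equal(
    compute_Di(rt, "p001", "neutral", "simultaneous"),
    manual,
    tolerance = 1e-12
  )
})

test_that("episodic factors reproduce the two-event worked example", {
  # event 1 scores 4/4 on the reference questions, event 2 scores 0/4;
  # both table questions split 1/0 so P = 0.5. With the guessing-corrected
  # factor (floor 1/6): E = (e - 1/6) / (1/2 - 1/6) = (2.5, -0.5), and the
  # adjusted probabilities are E * (1/2 - 1/6) + 1/6 = (1, 0).
  q <- matrix(0L, 2, 6, dimnames = list(
    c("ev1", "ev2"), all_question_names()
  ))
  q[1, ] <- 1L
  rt <- rt_from_qmat(q)
  ef <- episodic_factors(rt, "p001", "neutral", "simultaneous",
    table_kind = "cue_common", common_category = "person",
    P_G = 1, n_choices = 6
  )
  expect_equal(ef$E, c(2.5, -0.5))
  expect_equal(ef$p_adj_1, c(1, 0), tolerance = 1e-12)

  # fully dependent two-event data: the Dependent model matches the observed
  # dependency exactly while the Independent model sits at chance agreement
  expect_equal(
    compute_Dd(rt, "p001", "neutral", "simultaneous", P_G = 1), 1,
    tolerance = 1e-12
  )
  tabs <- build_contingency_tables(rt, "p001", "neutral", "simultaneous")
  expect_equal(compute_D(tabs), 1)
  expect_equal(compute_Di(rt, "p001", "neutral", "simultaneous"), 0.5)

  # with no guessing correction (P_G = 0) the factor is the plain
  # performance ratio: E = (1, 0) / 0.5 = (2, 0)
  ef0 <- episodic_factors(rt, "p001", "neutral", "simultaneous",
    table_kind = "cue_common", common_category = "person",
    P_G = 0, n_choices = 6
  )
  expect_equal(ef0$E, c(2, 0))
})

test_that("unit episodic factors collapse the Dependent onto the Independent model", {
  for (s in 1:5) {
    rt <- random_rt(15, p = runif(1, 0.3, 0.9), seed = 500 + s)
    di <- compute_Di(rt, "p001", "neutral", "simultaneous")
    dd <- compute_Dd(rt, "p001", "neutral", "simultaneous",
      force_unit_E = TRUE
    )
    expect_equal(dd, di, tolerance = 1e-12)
  }
})

test_that("a degenerate reference (all-zero cell) is reported", {
  q <- matrix(0L, 3, 6, dimnames = list(NULL, all_question_names()))
  rt <- rt_from_qmat(q)
  expect_error(
    compute_Dd(rt, "p001", "neutral", "simultaneous"),
    "degenerate reference"
  )
})

test_that("dependency measures are invariant to relabelling within tables", {
  rt <- random_rt(20, p = 0.6, seed = 11)
  swap <- function(x) {
    out <- x
    out[x == "location"] <- "object"
    out[x == "object"] <- "location"
    out
  }
  rt2 <- rt
  rt2$cue_category <- swap(rt2$cue_category)
  rt2$target_category <- swap(rt2$target_category)
  tabs1 <- build_contingency_tables(rt, "p001", "neutral", "simultaneous")
  tabs2 <- build_contingency_tables(rt2, "p001", "neutral", "simultaneous")
  expect_equal(compute_D(tabs1), compute_D(tabs2))
  expect_equal(
    compute_Di(rt, "p001", "neutral", "simultaneous"),
    compute_Di(rt2, "p001", "neutral", "simultaneous")
  )
  expect_equal(
    compute_Dd(rt, "p001", "neutral", "simultaneous"),
    compute_Dd(rt2, "p001", "neutral", "simultaneous")
  )
})

test_that("D, Di, Dd stay in [0, 1] across random tables", {
  for (s in 1:10) {
    rt <- random_rt(10, p = runif(1, 0.1, 0.95), seed = 700 + s)
    tabs <- build_contingency_tables(rt, "p001", "neutral", "simultaneous")
    d <- compute_D(tabs)
    di <- compute_Di(rt, "p001", "neutral", "simultaneous")
    dd <- tryCatch(
      compute_Dd(rt, "p001", "neutral", "simultaneous"),
      error = function(e) NA_real_
    )
    expect_true(d >= 0 && d <= 1)
    expect_true(di >= 0 && di <= 1)
    if (!is.na(dd)) expect_true(dd >= 0 && dd <= 1)
  }
})

test_that("accuracy_summary collapses directions and flags bad cells", {
  q <- matrix(0L, 4, 6, dimnames = list(NULL, all_question_names()))
  q[, "location.object"] <- 1L # one direction perfect, reverse at zero
  rt <- rt_from_qmat(q)
  acc <- accuracy_summary(rt)
  lo <- acc$accuracy[acc$pair_type == "location-object"]
  expect_equal(lo, 0.5)
  expect_equal(nrow(acc), 3)
  expect_error(accuracy_summary(rt[-1, ]), "not 6")

  allc <- rt_from_qmat(matrix(1L, 3, 6,
    dimnames = list(NULL, all_question_names())
  ))
  expect_true(all(accuracy_summary(allc)$accuracy == 1))
})

test_that("dependency_report aggregates per condition with standard errors", {
  rt <- dplyr::bind_rows(
    random_rt(12, p = 0.7, seed = 21, participant = "p001"),
    random_rt(12, p = 0.7, seed = 22, participant = "p002"),
    random_rt(12, p = 0.7, seed = 23, participant = "p003")
  )
  rep <- dependency_report(rt)
  expect_equal(nrow(rep$by_participant), 3)
  expect_equal(rep$summary$n_participants, 3)
  expect_equal(
    rep$summary$D_mean,
    mean(rep$by_participant$D)
  )
  expect_true(is.finite(rep$summary$D_minus_Di_se))
})
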