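# Filter cascade: worked examples with constructed read counts, threshold
# tie behaviour, cascade precedence, oracle agreement and parameter
# recovery on simulated trios.

make_calls <- function(chrom = "G1", pos = 100L, ref = "A", alt = "T",
                       depth, alt_depth, consequence = "missense",
                       distance_to_exon = 0) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = chrom,
             consequence = consequence, distance_to_exon = distance_to_exon,
             depth = depth, alt_depth = alt_depth, stringsAsFactors = FALSE)
}

no_calls <- data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       gene = character(0), consequence = character(0),
                       distance_to_exon = numeric(0), depth = integer(0),
                       alt_depth = integer(0), stringsAsFactors = FALSE)

one_variant_trio <- function(sens = NULL, low = NULL, high = NULL, ...) {
  mk <- function(x) if (is.null(x)) no_calls else
    make_calls(depth = x[1], alt_depth = x[2], ...)
  list(sensitive = mk(sens), low = mk(low), high = mk(high),
       drug = "imatinib", replicate = 1L)
}

test_that("an acquired high-dose variant passes and classifies (KRAS-G12D-like)", {
  tr <- filter_and_classify(one_variant_trio(high = c(41, 12)))
  expect_equal(tr$verdict, "PASS")
  expect_equal(tr$clonal_class, "ACQUIRED_HIGH")
  expect_true(is.na(tr$vaf_sensitive) && is.na(tr$vaf_low))
  expect_equal(tr$vaf_high, 12 / 41)
  expect_false(tr$pass_low); expect_true(tr$pass_high)
})

test_that("a variant gained in both resistant lines is SHARED_CONSTANT (NRAS-like)", {
  tr <- filter_and_classify(one_variant_trio(low = c(72, 21),
                                             high = c(72, 24)))
  expect_equal(tr$verdict, "PASS")
  expect_equal(tr$clonal_class, "SHARED_CONSTANT")
  expect_true(tr$pass_low && tr$pass_high)
})

test_that("a subthreshold low-dose gain still classifies ACQUIRED_HIGH (KRAS-A59T-like)", {
  tr <- filter_and_classify(one_variant_trio(sens = c(1000, 0),
                                             low = c(1000, 87),
                                             high = c(60, 40)))
  # sensitive stage has zero alternate reads, so in practice no record: use
  # the emitted-records convention too
  tr2 <- filter_and_classify(one_variant_trio(low = c(1000, 87),
                                              high = c(60, 40)))
  for (t in list(tr, tr2)) {
    expect_equal(t$verdict, "PASS")
    expect_equal(t$clonal_class, "ACQUIRED_HIGH")
    expect_false(t$pass_low); expect_true(t$pass_high)
  }
})

test_that("variants dropping from low to high are SHARED_REDUCED_HIGH", {
  tr <- filter_and_classify(one_variant_trio(low = c(100, 40),
                                             high = c(100, 20)))
  expect_equal(tr$clonal_class, "SHARED_REDUCED_HIGH")
  tr2 <- filter_and_classify(one_variant_trio(low = c(100, 40),
                                              high = c(100, 30)))
  expect_equal(tr2$clonal_class, "SHARED_CONSTANT")
})

test_that("variants gained only in the low-dose line are LOW_ONLY", {
  tr <- filter_and_classify(one_variant_trio(low = c(100, 40)))
  expect_equal(tr$clonal_class, "LOW_ONLY")
})

test_that("small VAF drifts fail the delta filter", {
  tr <- filter_and_classify(one_variant_trio(sens = c(100, 4),
                                             low = c(100, 10),
                                             high = c(100, 12)))
  expect_equal(tr$verdict, "FAIL_delta")
  expect_equal(tr$clonal_class, "NONE")
})

test_that("variants already present in the sensitive line fail", {
  tr <- filter_and_classify(one_variant_trio(sens = c(100, 50),
                                             low = c(100, 55),
                                             high = c(100, 60)))
  expect_equal(tr$verdict, "FAIL_sensitive")
})

test_that("ties at the thresholds fail (strict comparisons)", {
  # delta exactly 0.15
  tr <- filter_and_classify(one_variant_trio(high = c(100, 15)))
  expect_equal(tr$verdict, "FAIL_delta")
  tr <- filter_and_classify(one_variant_trio(high = c(100, 16)))
  expect_equal(tr$verdict, "PASS")
  # sensitive VAF exactly 0.05 fails (>= threshold)
  tr <- filter_and_classify(one_variant_trio(sens = c(100, 5),
                                             high = c(100, 60)))
  expect_equal(tr$verdict, "FAIL_sensitive")
  tr <- filter_and_classify(one_variant_trio(sens = c(100, 4),
                                             high = c(100, 60)))
  expect_equal(tr$verdict, "PASS")
  # intronic distance exactly 20 is kept, 21 removed
  tr <- filter_and_classify(one_variant_trio(high = c(100, 60),
                                             consequence = "intronic",
                                             distance_to_exon = 21))
  expect_equal(tr$verdict, "FAIL_intronic")
  tr <- filter_and_classify(one_variant_trio(high = c(100, 60),
                                             consequence = "intronic",
                                             distance_to_exon = 20))
  expect_equal(tr$verdict, "PASS")
})

test_that("the coverage gate dominates the cascade", {
  # depths all below 10 -> FAIL_depth even though sensitive VAF is high
  tr <- filter_and_classify(one_variant_trio(sens = c(9, 8), low = c(9, 9),
                                             high = c(9, 9)))
  expect_equal(tr$verdict, "FAIL_depth")
  # one covered sample anywhere rescues the gate
  tr <- filter_and_classify(one_variant_trio(sens = c(10, 8), low = c(9, 9),
                                             high = c(9, 9)))
  expect_equal(tr$verdict, "FAIL_sensitive")
  # zero-depth calls never satisfy the gate even with min_depth = 0
  cfg0 <- filter_config(min_depth = 0L)
  tr <- filter_and_classify(one_variant_trio(high = c(0, 0)), cfg0)
  expect_equal(tr$verdict, "FAIL_depth")
})

test_that("cascade verdicts match a brute-force oracle (50 variants x 20 seeds)", {
  for (seed in 1:20) {
    case <- random_trio_case(n = 50, seed = seed)
    got <- filter_and_classify(case$trio)
    key <- paste(case$vars$chrom, case$vars$pos, case$vars$ref,
                 case$vars$alt, sep = ":")
    got_key <- paste(got$chrom, got$pos, got$ref, got$alt, sep = ":")
    called_any <- case$vars$called_s | case$vars$called_l |
      case$vars$called_h
    expect_setequal(got_key, key[called_any])
    oracle <- oracle_cascade(case$vars)
    m <- match(got_key, key)
    expect_identical(got$verdict, oracle$verdict[m],
                     label = paste("verdicts, seed", seed))
    expect_identical(got$clonal_class, oracle$clonal_class[m],
                     label = paste("classes, seed", seed))
  }
})

test_that("raising the high-dose VAF never turns a PASS into FAIL_delta", {
  base <- one_variant_trio(high = c(100, 20))
  verdicts <- vapply(20:100, function(a) {
    filter_and_classify(one_variant_trio(high = c(100, a)))$verdict
  }, "")
  expect_true(all(verdicts == "PASS"))
})

test_that("burden_table counts passing variants per subline", {
  trio <- list(
    sensitive = no_calls,
    low = rbind(make_calls(pos = 1L, depth = 100, alt_depth = 40),
                make_calls(pos = 2L, depth = 100, alt_depth = 30)),
    high = rbind(make_calls(pos = 2L, depth = 100, alt_depth = 30),
                 make_calls(pos = 3L, depth = 100, alt_depth = 50)),
    drug = "imatinib", replicate = 2L)
  tr <- filter_and_classify(trio)
  b <- burden_table(tr)
  expect_equal(b$subline, c("lowIM-R2", "highIM-R2"))
  expect_equal(b$n_pass, c(2L, 2L))           # pos 1+2 low, pos 2+3 high
  expect_equal(unique(b$n_pass_unique_trio), 3L)
  expect_equal(b$LOW_ONLY, c(1L, 0L))
  expect_equal(b$ACQUIRED_HIGH, c(0L, 1L))
  expect_equal(b$SHARED_CONSTANT, c(1L, 1L))
})

test_that("planted trajectories are recovered exactly at depth 10,000", {
  fx <- fx_hidepth()
  for (nm in names(fx$trios)) {
    sim <- fx$trios[[nm]]
    trio <- trio_from_sim(sim, fx$re$exons)
    tr <- filter_and_classify(trio)
    truth <- sim$truth
    drivers <- truth[truth$kind == "driver", ]
    k_tr <- variant_key(tr$chrom, tr$pos, tr$ref, tr$alt)
    k_d <- variant_key(drivers$chrom, drivers$pos, drivers$ref, drivers$alt)
    m <- match(k_d, k_tr)
    expect_false(anyNA(m))
    expect_identical(tr$clonal_class[m], drivers$true_class,
                     label = paste("driver classes,", nm))
  }
})

test_that("true gains of at least 0.25 are recovered at depth 60", {
  fx <- fx_pipeline()
  truth <- fx$res$manifest$truth
  traj <- fx$res$trajectories
  k_truth <- paste(truth$drug, truth$replicate,
                   variant_key(truth$chrom, truth$pos, truth$ref,
                               truth$alt))
  k_traj <- paste(traj$drug, traj$replicate,
                  variant_key(traj$chrom, traj$pos, traj$ref, traj$alt))
  vs0 <- ifelse(is.na(truth$vaf_sensitive), 0, truth$vaf_sensitive)
  vl0 <- ifelse(is.na(truth$vaf_low), 0, truth$vaf_low)
  vh0 <- ifelse(is.na(truth$vaf_high), 0, truth$vaf_high)
  strong <- vs0 == 0 & pmax(vl0, vh0) - vs0 >= 0.25 &
    truth$consequence != "intronic"
  m <- match(k_truth[strong], k_traj)
  verdicts <- traj$verdict[m]
  verdicts[is.na(verdicts)] <- "ABSENT"
  expect_gte(mean(verdicts == "PASS"), 0.9)
})
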