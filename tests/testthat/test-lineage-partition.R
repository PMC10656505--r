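test_that("node calls threshold per-trait marginals", {
  p <- rbind(c(0.9, 0.05, 0.03, 0.02),
             c(0.4, 0.3, 0.2, 0.1),
             c(0.25, 0.25, 0.25, 0.25))
  colnames(p) <- lineage_states()
  calls <- assign_node_states(p, threshold = 0.7)
  expect_equal(calls$symbiosis[1], "azoox")
  expect_equal(calls$coloniality[1], "solitary")
  # row 2: azoox marginal 0.7 (called), solitary marginal 0.6 (uncertain)
  expect_equal(calls$symbiosis[2], "azoox")
  expect_equal(calls$coloniality[2], "uncertain")
  expect_equal(calls$symbiosis[3], "uncertain")
  expect_equal(calls$coloniality[3], "uncertain")
  expect_error(assign_node_states(p, threshold = 0.5), "threshold")
})

test_that("branch classification merges statuses per the eight-category table", {
  # chain of cherries so specific parent/child call pairs are easy to stage
  tr <- read_timetree("((A:1,B:1):1,(C:1,D:1):1);")
  calls <- data.frame(
    node_id = 1:7,
    symbiosis  = c("azoox", "azoox", "zoox", "uncertain",
                   "azoox", "azoox", "azoox"),
    coloniality = c("solitary", "uncertain", "colonial", "colonial",
                    "solitary", "solitary", "colonial"),
    stringsAsFactors = FALSE)
  cb <- classify_branches(tr, calls)
  by_child <- stats::setNames(cb$category, cb$descendant)
  expect_equal(by_child[["1"]], "AS")        # azoox-solitary at both ends
  expect_equal(by_child[["2"]], "UncC")      # azoox, uncertain coloniality
  expect_equal(by_child[["3"]], "TransS")    # azoox->zoox, colonial assigned
  expect_equal(by_child[["4"]], "UncS")      # uncertain symbiosis, colonial
  expect_equal(by_child[["7"]], "TransC")    # azoox stable, solitary->colonial
  expect_true(all(table(cb$category) >= 1))
})

test_that("the excluded raw combinations are logged, and counts partition", {
  tr <- read_timetree("((A:1,B:1):1,C:2);")
  calls <- data.frame(
    node_id = 1:5,
    symbiosis = c("zoox", "uncertain", "azoox", "azoox", "azoox"),
    coloniality = c("colonial", "solitary", "solitary", "solitary", "solitary"),
    stringsAsFactors = FALSE)
  # branch to A: azoox->zoox with solitary->colonial: transition-transition
  # branch to B: azoox->uncertain with solitary: uncertain-solitary
  cb <- classify_branches(tr, calls)
  excl <- attr(cb, "excluded")
  expect_equal(nrow(excl), 2L)
  expect_setequal(excl$raw_label,
                  c("transition-transition", "uncertain-solitary"))
  expect_equal(sum(!is.na(cb$category)) + nrow(excl), nrow(tr$edge))
})

test_that("the published raw-count table merges to the category totals", {
  tab1 <- data.frame(
    symbiosis_status = c("azoox", "azoox", "zoox", "zoox",
                         "transition", "transition", "transition",
                         "azoox", "zoox",
                         "uncertain", "uncertain",
                         "azoox", "zoox"),
    coloniality_status = c("solitary", "colonial", "solitary", "colonial",
                           "solitary", "colonial", "uncertain",
                           "transition", "transition",
                           "colonial", "uncertain",
                           "uncertain", "uncertain"),
    n = c(195, 38, 52, 610, 1, 9, 13, 4, 12, 6, 1, 64, 13))
  merged <- merge_category_counts(tab1)
  expect_equal(unname(merged["TransS"]), 23)
  expect_equal(unname(merged["TransC"]), 16)
  expect_equal(unname(merged["UncS"]), 7)
  expect_equal(unname(merged["UncC"]), 77)
  expect_equal(unname(merged[c("AS", "AC", "ZS", "ZC")]),
               c(195, 38, 52, 610))
  expect_equal(sum(merged), sum(tab1$n))
})

test_that("degenerate posteriors recover the true per-branch categories", {
  tr <- simulate_tree(50, seed = 701)
  trc <- tr
  trc$edge.length <- trc$edge.length / max(node_ages(tr)) * 2
  trc <- timetree(trc)
  Q <- correlated_Q(rep(0.25, 8))
  sim <- simulate_correlated_traits(trc, Q, "AS", seed = 702)
  ntot <- 50 + trc$Nnode
  probs <- matrix(0, ntot, 4, dimnames = list(NULL, lineage_states()))
  probs[cbind(seq_len(ntot), match(sim$node_states, lineage_states()))] <- 1
  calls <- assign_node_states(probs, threshold = 0.999)
  cb <- classify_branches(trc, calls)
  truth_anc <- sim$node_states[trc$edge[, 1]]
  truth_dec <- sim$node_states[trc$edge[, 2]]
  stable <- truth_anc == truth_dec
  expect_equal(cb$category[stable], truth_dec[stable])
  symb_t <- substr(truth_anc, 1, 1) != substr(truth_dec, 1, 1)
  col_t <- substr(truth_anc, 2, 2) != substr(truth_dec, 2, 2)
  expect_true(all(cb$category[symb_t & !col_t] == "TransS"))
  expect_true(all(cb$category[col_t & !symb_t] == "TransC"))
  expect_true(all(is.na(cb$category[symb_t & col_t])))
})
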