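# Read processing: anchor mapping, poly(A)-run cleavage calls, UMI
# collapsing, isoform estimation and the internal-priming filter.

test_that("anchor mapping tolerates at most two substitutions", {
  set.seed(90)
  refs <- setNames(random_seq(3), c("r1", "r2", "r3"))
  read <- paste0(substr(refs["r2"], 1, 60), strrep("A", 25))
  expect_equal(mapRead(read, refs), "r2")
  mutate_prefix <- function(r, k) {
    for (pos in sample(30, k)) {
      r <- substituteBase(r, pos - 1L,
                          setdiff(c("A", "C", "G", "T"),
                                  substr(r, pos, pos))[1])
    }
    r
  }
  expect_equal(mapRead(mutate_prefix(read, 2), refs), "r2")
  expect_true(is.na(mapRead(mutate_prefix(read, 3), refs)))
  # ambiguity: two references sharing an anchor leave the read unmapped
  refs_amb <- c(a = refs[["r1"]],
                b = paste0(substr(refs[["r1"]], 1, 30),
                           substr(refs[["r2"]], 31, 205)))
  expect_true(is.na(mapRead(paste0(substr(refs[["r1"]], 1, 50), "AAAA"),
                            refs_amb)))
  # vectorized mapping agrees with the scalar rule and ignores order
  reads <- c(read, mutate_prefix(read, 3),
             paste0(substr(refs["r3"], 1, 40), strrep("A", 22)))
  m1 <- polyacode:::mapReads(reads, refs)
  m2 <- polyacode:::mapReads(rev(reads), refs)
  expect_identical(m1, rev(m2))
  expect_identical(m1, c("r2", NA, "r3"))
})

test_that("cleavage sites are called at the first tolerant poly(A) window", {
  set.seed(91)
  ref30 <- paste(sample(c("C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
  expect_equal(findCleavageSite(paste0(ref30, strrep("A", 20))), 30L)
  # two non-A bases inside the run are tolerated
  run2 <- paste0(strrep("A", 9), "C", strrep("A", 5), "G", strrep("A", 4))
  expect_equal(findCleavageSite(paste0(ref30, run2)), 30L)
  # three are not
  run3 <- paste0(strrep("A", 5), "C", strrep("A", 5), "G",
                 strrep("A", 5), "T", strrep("A", 3))
  expect_true(is.na(findCleavageSite(paste0(ref30, run3))))
  expect_true(is.na(findCleavageSite(ref30)))
  # strict mode requires a clean run
  expect_true(is.na(findCleavageSite(paste0(ref30, run2),
                                     max_mismatch = 0L)))
  # the search is 5' to 3': the first qualifying window wins
  double <- paste0(ref30, strrep("A", 20), ref30, strrep("A", 20))
  expect_equal(findCleavageSite(double), 30L)
})

test_that("UMI collapsing counts molecules once and pools replicates", {
  calls <- data.frame(
    reference = c("r1", "r1", "r1", "r1", "r1", "r2"),
    site = c(40L, 40L, 40L, 55L, NA, 40L),
    umi = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT",
            "AAAAAAAA"),
    replicate = 1L)
  r <- collapseUmis(calls)
  # 3 duplicates of one UMI count once; same UMI in another reference counts
  expect_equal(sum(r$table$count[r$table$reference == "r1"]), 4L)
  expect_equal(r$table$count[r$table$reference == "r2"], 1L)
  expect_equal(nrow(r$conflicts), 0L)
  # a UMI collision with divergent sites keeps the first and logs it
  calls2 <- rbind(calls,
                  data.frame(reference = "r1", site = 90L, umi = "AAAAAAAA",
                             replicate = 1L))
  r2 <- collapseUmis(calls2)
  expect_equal(nrow(r2$conflicts), 1L)
  expect_false(90L %in% r2$table$site)
  # collapsing twice is idempotent
  expanded <- r$table[rep(seq_len(nrow(r$table)), r$table$count), ]
  expanded$umi <- paste0("U", seq_len(nrow(expanded)))
  r3 <- collapseUmis(expanded)
  expect_equal(sum(r3$table$count), sum(r$table$count))
  # replicate pooling sums per-replicate tables
  two_rep <- rbind(calls, transform(calls, replicate = 2L))
  pooled <- collapseUmis(two_rep, pool_replicates = TRUE)
  expect_equal(sum(pooled$table$count), 2L * sum(r$table$count))
})

test_that("error-free synthetic reads reproduce the truth table exactly", {
  b <- tiny_bundle(n = 25, seed = 92, depth = 40)
  rd <- generateReads(b, reads_per_record = 25, seed = 93)
  refs <- setNames(pasSequences(b), as.character(seq_len(25)))
  pr <- processReads(rd$read1, rd$read2, refs, run_mismatch = 0L)
  expect_equal(pr$n_unmapped, 0L)
  tt <- rd$truth
  tt <- tt[!duplicated(paste(tt$record, tt$umi)), ]
  key <- function(ref, site) paste(ref, ifelse(is.na(site), "distal", site))
  truth_tab <- table(key(tt$record, tt$site))
  got_tab <- setNames(pr$table$count, key(pr$table$reference, pr$table$site))
  expect_setequal(names(truth_tab), names(got_tab))
  expect_equal(unname(got_tab[names(truth_tab)]),
               unname(as.integer(truth_tab)))
})

test_that("isoform estimation applies the replicate filter and window", {
  # all counts proximal and inside the window: proportion 1
  tab <- data.frame(reference = "r1", site = c(75L, 90L, 110L),
                    replicate = 1L, count = c(10L, 5L, 5L))
  est <- estimateIsoforms(tab, cse_offset = 69L, window = c(0L, 50L))
  expect_equal(est$proportions$proportion, 1)
  # a pair whose member falls below the UMI filter is excluded
  tab2 <- rbind(tab, data.frame(reference = "r2", site = 90L,
                                replicate = 1L, count = 150L))
  pairs <- data.frame(wt = "r2", var = "r1")
  est2 <- estimateIsoforms(tab2, pairs = pairs, min_mean_umi = 200,
                           min_replicates = 1L)
  expect_true(est2$pairs$excluded)
  est3 <- estimateIsoforms(tab2, pairs = pairs, min_mean_umi = 10,
                           min_replicates = 1L)
  expect_false(est3$pairs$excluded)
  expect_true(is.finite(est3$pairs$lor))
  # end to end: proportions match the generating cleavage law within
  # multinomial error
  law <- defaultLaw()
  b <- generatePASLibrary(10, law, seed = 94, depth = 30)
  rd <- generateReads(b, reads_per_record = 200, seed = 95)
  refs <- setNames(pasSequences(b), as.character(seq_len(10)))
  pr <- processReads(rd$read1, rd$read2, refs, run_mismatch = 0L)
  est4 <- estimateIsoforms(pr$table, cse_offset = 69L, window = c(7L, 58L))
  prox_true <- vapply(pasSequences(b), function(s) lawProximal(law, s),
                      numeric(1), USE.NAMES = FALSE)
  got <- est4$proportions$proportion[
    order(as.integer(est4$proportions$reference))]
  se <- sqrt(prox_true * (1 - prox_true) / 200)
  expect_true(all(abs(got - prox_true) < 4 * se + 0.02))
})

test_that("the internal-priming filter uses a strict 75% window rule", {
  # 10 A's in a 12-bp window (83% > 75%): removed
  rich <- paste0(strrep("C", 90), strrep("A", 10), strrep("C", 105))
  expect_equal(nchar(rich), 205L)
  # 9 A's in a 12-bp window (exactly 75%): retained under the strict rule
  edge <- paste0(strrep("C", 90), strrep("A", 9), strrep("C", 106))
  expect_equal(nchar(edge), 205L)
  plain <- paste(rep(c("A", "C", "G", "T"), length.out = 205),
                 collapse = "")
  r <- internalPrimingFilter(c(rich, edge, plain))
  expect_identical(r$removed, rich)
  expect_identical(r$retained, c(edge, plain))
})
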