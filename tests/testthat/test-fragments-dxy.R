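test_that("fragment starts follow the window arithmetic", {
  seqs <- flat_seqs(c("s1", "s2"), 100000)
  substr(seqs$s2[["chr1"]], 500, 500) <- "T"   # make fragment 1 variable
  fs <- sample_fragments(seqs)
  expect_equal(fs$fragments$start, c(0, 20000, 40000, 60000, 80000))
  expect_equal(fs$fragments$end - fs$fragments$start, rep(1000, 5))
  expect_equal(fs$fragments$status,
               c("kept", rep("monomorphic", 4)))
})

test_that("ambiguity and monomorphy rules drop fragments", {
  seqs <- flat_seqs(c("s1", "s2"), 50000)
  # plant 51 Ns in sample 1's second fragment: discarded
  substr(seqs$s1[["chr1"]], 20001, 20051) <- strrep("N", 51)
  # 50 Ns in the first fragment: tolerated, but needs a variable column
  substr(seqs$s1[["chr1"]], 1, 50) <- strrep("N", 50)
  substr(seqs$s2[["chr1"]], 600, 600) <- "G"
  fs <- sample_fragments(seqs)
  expect_equal(fs$fragments$status, c("kept", "ambiguous", "monomorphic"))
  # identical samples: nothing variable anywhere
  fs0 <- sample_fragments(flat_seqs(c("a", "b", "c"), 60000))
  expect_equal(sum(fs0$fragments$status == "kept"), 0)
  # a column containing N in any sample cannot count as variable
  seqs2 <- flat_seqs(c("x", "y"), 30000)
  substr(seqs2$x[["chr1"]], 100, 100) <- "N"
  substr(seqs2$y[["chr1"]], 100, 100) <- "T"
  expect_equal(sample_fragments(seqs2)$fragments$status[1], "monomorphic")
  # unequal lengths error
  bad <- list(a = c(chr1 = strrep("A", 1000)),
              b = c(chr1 = strrep("A", 1200)))
  expect_error(sample_fragments(bad), "identical")
})

test_that("kept fragments are written as per-locus FASTA alignments", {
  seqs <- flat_seqs(c("s1", "s2"), 25000)
  substr(seqs$s2[["chr1"]], 10, 10) <- "C"
  substr(seqs$s2[["chr1"]], 20010, 20010) <- "C"
  fs <- sample_fragments(seqs)
  d <- tempfile()
  paths <- write_fragment_fastas(fs, d)
  expect_equal(length(paths), 2)
  aln <- Biostrings::readDNAStringSet(paths[1])
  expect_equal(names(aln), c("s1", "s2"))
  expect_equal(unique(Biostrings::width(aln)), 1000)
})

test_that("dxy equals brute-force copy-pair enumeration", {
  # diploid {0,1} vs tetraploid {0,0,0,1}: 8 copy pairs, 4 differ
  vm <- toy_vm(matrix(c("0/1", "0/0/0/1"), 1, 2), ploidy = c(2L, 4L))
  brute <- mean(outer(c(0, 1), c(0, 0, 0, 1), "!="))
  expect_equal(brute, 0.5)
  expect_equal(unname(dxy(vm, c("g1", "g2"))["g1", "g2"]), brute)
  # groups fixed for the same allele at every site diverge by zero
  fixed <- rep(c("0/0", "1/1"), length.out = 5)
  vm0 <- toy_vm(cbind(fixed, fixed), c(2L, 2L), pos = 1:5)
  expect_equal(unname(dxy(vm0, c("a", "b"))["a", "b"]), 0)
  # shared polymorphism keeps Dxy positive even for identical groups:
  # copies {0,1} vs {0,1} differ in 2 of 4 pairs
  vm_het <- toy_vm(matrix("0/1", 1, 2), c(2L, 2L))
  expect_equal(unname(dxy(vm_het, c("a", "b"))["a", "b"]), 0.5)
  # randomized oracle: per-site enumeration over all copy pairs
  set.seed(97)
  for (rep in 1:5) {
    gts <- replicate(6, {
      a <- sample(0:2, 1); b <- sample(0:4, 1)
      c(paste(c(rep("0", 2 - a), rep("1", a)), collapse = "/"),
        paste(c(rep("0", 4 - b), rep("1", b)), collapse = "/"))
    })
    vmr <- toy_vm(t(gts), ploidy = c(2L, 4L), pos = 1:6)
    brute <- mean(vapply(seq_len(6), function(i) {
      c1 <- as.integer(strsplit(vmr$gt[i, 1], "/")[[1]])
      c2 <- as.integer(strsplit(vmr$gt[i, 2], "/")[[1]])
      mean(outer(c1, c2, "!="))
    }, 0))
    got <- dxy(vmr, c("p", "q"))
    expect_equal(unname(got["p", "q"]), brute, tolerance = 1e-12)
    expect_equal(got["p", "q"], got["q", "p"])
  }
})

test_that("dxy scales linearly with the fixed-difference fraction", {
  for (k in c(1, 3, 7)) {
    gt <- matrix(rep(c("0/0", "0/0/0/0"), each = 10), 10, 2)
    gt[seq_len(k), 1] <- "1/1"   # group 1 fixed alt at k of 10 sites
    vm <- toy_vm(gt, ploidy = c(2L, 4L), pos = 1:10)
    expect_equal(unname(dxy(vm, c("a", "b"))["a", "b"]), k / 10)
  }
  # a group with no called copies at any site errors
  vm_bad <- toy_vm(matrix(c("0/1", "./."), 1, 2), c(2L, 2L))
  expect_error(dxy(vm_bad, c("a", "b")), "zero non-missing")
})

test_that("missing copies are skipped pairwise-complete", {
  # site 1: group b fully missing -> only site 2 informs the pair,
  # but the site average still divides by all supplied sites
  gt <- rbind(c("0/0", "./."), c("1/1", "0/0"))
  vm <- toy_vm(gt, c(2L, 2L), pos = 1:2)
  expect_equal(unname(dxy(vm, c("a", "b"))["a", "b"]), 0.5)
})

test_that("STRUCTURE coding pads diploids with -9 rows", {
  vm <- toy_vm(matrix(c("0/1", "0/0/1/1"), 1, 2), ploidy = c(2L, 4L))
  m <- write_structure(vm)
  expect_equal(nrow(m), 8)  # 4 rows per individual
  expect_equal(unname(m[1:4, 1]), c(0L, 1L, -9L, -9L))
  expect_equal(unname(m[5:8, 1]), c(0L, 0L, 1L, 1L))
  # missing genotypes are -9 across the sample's real rows too
  vm2 <- toy_vm(matrix(c("./.", "0/0/0/1"), 1, 2), ploidy = c(2L, 4L))
  expect_equal(unname(write_structure(vm2)[1:4, 1]), rep(-9L, 4))
  # file output: one line per allele-copy row, label first
  p <- tempfile()
  write_structure(vm, p)
  lines <- readLines(p)
  expect_equal(length(lines), 8)
  expect_match(lines[1], "^S1 0$")
  expect_match(lines[3], "^S1 -9$")
})
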