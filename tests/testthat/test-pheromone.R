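# ORF finding, CaaX/CpaX motif scanning, proximity filtering and the
# planted-fixture recovery.

# a 150 bp ORF (incl. TAA stop) whose peptide is M D ... E R ...9aa... C V I A
demo_orf <- function() {
  paste0("ATGGAT", strrep("GGT", 32), "GAACGT", strrep("GGT", 9),
         "TGTGTTATTGCT", "TAA")
}

test_that("planted ORFs are found with exact coordinates on both strands", {
  orf <- demo_orf()
  set.seed(2)
  pad1 <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  pad2 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  contig <- paste0(pad1, orf, pad2)
  hits <- find_orfs(contig, 100, 200)
  fwd <- hits[hits$start == 501 & hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$end, 500L + nchar(orf))
  expect_equal(fwd$orf_len_bp, 150L)
  expect_match(fwd$peptide, "^MD")
  expect_match(fwd$peptide, "CVIA$")

  # the same ORF on the reverse strand maps back to the forward axis
  rc <- matloci:::revcomp(contig)
  rhits <- find_orfs(rc, 100, 200)
  want_start <- nchar(contig) - (500L + nchar(orf)) + 1L
  want_end <- nchar(contig) - 501L + 1L
  expect_true(any(rhits$strand == "-" & rhits$start == want_start &
                    rhits$end == want_end))

  expect_error(find_orfs("ACGTXACGT"), "non-DNA")
})

test_that("ORFs outside the length window are absent from the output", {
  short_orf <- paste0("ATGGAT", strrep("GGT", 27), "TAA")  # 90 bp
  contig <- paste0(strrep("C", 300), short_orf, strrep("C", 300))
  hits <- find_orfs(contig, 100, 200)
  expect_false(any(hits$start == 301 & hits$strand == "+"))
  # visible when the window admits it
  hits2 <- find_orfs(contig, 60, 200)
  expect_true(any(hits2$start == 301 & hits2$strand == "+"))
})

test_that("nested in-frame ORFs are reported independently", {
  inner_start <- "ATG"
  orf <- paste0("ATGGAT", strrep("GGT", 20), inner_start, strrep("GCT", 20),
                "TAA")  # outer 195 bp, inner 66+... both end at the same stop
  contig <- paste0(strrep("C", 99), orf, strrep("C", 99))
  hits <- find_orfs(contig, 60, 200)
  same_stop <- hits[hits$strand == "+" & hits$end == 99L + nchar(orf), ]
  expect_gte(nrow(same_stop), 2L)
})

test_that("motif classification follows the CaaX / CpaX rules", {
  caax <- scan_precursor("MDGGGGERGGGGGGGGGCVIA")
  expect_equal(caax$motif_kind, "CaaX")
  expect_equal(caax$maturation, "ER")
  # mature peptide: residue after the maturation R through the motif C
  expect_equal(caax$mature_peptide, "GGGGGGGGGC")
  expect_equal(caax$mature_len, 10L)

  cpax <- scan_precursor("MDGGGGDRGGGGGGGGGCTIS")
  expect_equal(cpax$motif_kind, "CpaX")
  expect_equal(cpax$maturation, "DR")

  expect_equal(scan_precursor("MDGGGGERGGGGGGGGGCGGS")$motif_kind, "none")
  expect_equal(scan_precursor("MCVIA")$motif_kind, "none")  # too short
  # rightmost maturation dipeptide wins
  two_er <- scan_precursor("MDERGGGGERGGGGGGGGGCVIA")
  expect_equal(two_er$maturation_pos, 9L)
  # polar set is configurable
  expect_equal(scan_precursor("MDGGGGERGGGGGGGGGCSIA")$motif_kind, "none")
  expect_equal(scan_precursor("MDGGGGERGGGGGGGGGCSIA",
                              polar_set = c("S", "T"))$motif_kind, "CpaX")
})

test_that("proximity filtering accepts near hits and rejects far ones", {
  feats <- data.frame(contig = "c1", start = c(10000L, 30000L),
                      end = c(11000L, 31000L), strand = "+",
                      feature_id = c("STE3.2", "STE3.4"), kind = "STE3",
                      stringsAsFactors = FALSE)
  hits <- data.frame(start = c(13000L, 51000L), end = c(13149L, 51149L),
                     strand = "+", motif_kind = c("CaaX", "CaaX"),
                     mature_len = c(10L, 10L), nearest_ste3_id = NA_character_,
                     distance_bp = NA_integer_, mature_len_warn = NA,
                     verdict = NA_character_, stringsAsFactors = FALSE)
  out <- proximity_filter(hits, feats, max_dist_bp = 5000, contig_name = "c1")
  expect_equal(out$verdict, c("accepted", "rejected(distance)"))
  expect_equal(out$distance_bp[1], 13000L - 11000L - 1L)
  expect_false(out$mature_len_warn[1])

  # overlapping ORF has distance 0
  hits0 <- hits[1, ]; hits0$start <- 10500L; hits0$end <- 10649L
  expect_equal(proximity_filter(hits0, feats, contig_name = "c1")$distance_bp, 0L)

  # no STE3 on the contig: everything rejected, with a warning
  expect_warning(out2 <- proximity_filter(hits, feats, contig_name = "c9"),
                 "no STE3")
  expect_true(all(out2$verdict == "rejected(distance)"))

  # out-of-band mature peptide is accepted but flagged
  hits3 <- hits[1, ]; hits3$mature_len <- 20L
  out3 <- proximity_filter(hits3, feats, contig_name = "c1")
  expect_equal(out3$verdict, "accepted")
  expect_true(out3$mature_len_warn)
})

test_that("the scanner recovers exactly the planted truth set", {
  fx <- plant_pheromone_fixture(seed = 4)
  hits <- scan_pheromones(fx$contig, fx$features)
  acc <- hits[hits$verdict == "accepted", ]
  want <- fx$truth[fx$truth$expected_verdict == "accepted", ]
  key <- function(s, e, st) sort(paste(s, e, st))
  expect_identical(key(acc$orf_start, acc$orf_end, acc$strand),
                   key(want$start, want$end, want$strand))
  # the CpaX precursor is reported as CpaX, not CaaX
  cpax_row <- merge(acc, fx$truth[fx$truth$class == "true_cpax", ],
                    by.x = "orf_start", by.y = "start")
  expect_equal(cpax_row$motif_kind, "CpaX")
  # decoys: absent (length) or rejected (distance / motif)
  distant <- fx$truth[fx$truth$class == "decoy_distant", ]
  dh <- hits[hits$orf_start == distant$start & hits$strand == distant$strand, ]
  expect_equal(dh$verdict, "rejected(distance)")
  expect_false(any(acc$orf_len_bp < 100 | acc$orf_len_bp > 200))
})

test_that("every accepted peptide ends with the motif cysteine at len-3", {
  fx <- plant_pheromone_fixture(seed = 4)
  acc <- scan_pheromones(fx$contig, fx$features)
  acc <- acc[acc$verdict == "accepted", ]
  for (pep in acc$peptide)
    expect_equal(substr(pep, nchar(pep) - 3L, nchar(pep) - 3L), "C")
})

test_that("scanning is strand-symmetric under reverse complement", {
  fx <- plant_pheromone_fixture(seed = 4)
  L <- nchar(fx$contig)
  feats_rc <- fx$features
  feats_rc$start <- L - fx$features$end + 1L
  feats_rc$end <- L - fx$features$start + 1L
  fwd <- scan_pheromones(fx$contig, fx$features)
  rev <- scan_pheromones(matloci:::revcomp(fx$contig), feats_rc)
  fa <- fwd[fwd$verdict == "accepted", ]
  ra <- rev[rev$verdict == "accepted", ]
  expect_setequal(paste(L - fa$orf_end + 1L, L - fa$orf_start + 1L),
                  paste(ra$orf_start, ra$orf_end))
  expect_setequal(ra$motif_kind, fa$motif_kind)
})

test_that("scanner output is sorted deterministically", {
  fx <- plant_pheromone_fixture(seed = 4)
  h1 <- scan_pheromones(fx$contig, fx$features)
  h2 <- scan_pheromones(fx$contig, fx$features)
  expect_identical(h1, h2)
  expect_false(is.unsorted(h1$orf_start))
})
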