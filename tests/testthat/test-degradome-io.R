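# Proteome/evidence readers and D|X cleavage-event derivation.

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("FASTA proteomes parse with accession and case normalisation", {
  f <- write_tmp(c(">sp|P12345|NAME1 some description", "mairgd", "SDGVDK",
                   ">Q00001 another", "MKLVDD"), ".fasta")
  prot <- read_proteome(f)
  expect_named(prot, c("P12345", "Q00001"))
  expect_equal(unname(prot["P12345"]), "MAIRGDSDGVDK")
  expect_equal(unname(prot["Q00001"]), "MKLVDD")
  dup <- write_tmp(c(">A1", "MAD", ">A1", "MED"), ".fasta")
  expect_error(read_proteome(dup), "duplicate accession")
})

test_that("cleavage events are derived from peptides preceded by aspartate", {
  prot <- c(P1 = "MAIRGDSDGVDK")
  ev <- data.frame(replicate = "rep1", peptide = "SDGVDK",
                   accession = "P1", stringsAsFactors = FALSE)
  out <- extract_cleavage_sites(ev, prot)
  expect_equal(nrow(out), 1)
  expect_equal(out$p1, 6L)
  expect_equal(out$context, "IRGDSDGV")
  # residue before the peptide is E: no event
  prot2 <- c(P1 = "MAIRGESDGVDK")
  expect_equal(nrow(extract_cleavage_sites(ev, prot2)), 0)
  # p1 < 5 (no full P4 window): dropped
  ev2 <- data.frame(replicate = "rep1", peptide = "DGVDK",
                    accession = "P1", stringsAsFactors = FALSE)
  prot3 <- c(P1 = "MADDGVDK")
  expect_equal(nrow(extract_cleavage_sites(ev2, prot3)), 0)
  expect_error(extract_cleavage_sites(
    data.frame(replicate = "r", peptide = "AA", accession = "NOPE"), prot),
    "not in proteome")
})

test_that("stated start coordinates are verified and C-termini padded", {
  prot <- c(P1 = "MAIRGDSDGVDK")
  ev <- data.frame(replicate = "r1", peptide = "K", accession = "P1",
                   start = 12L, stringsAsFactors = FALSE)
  out <- extract_cleavage_sites(ev, prot)
  expect_equal(out$p1, 11L)
  expect_equal(out$context, "DGVDKXXX")  # padded past the C terminus
  bad <- ev; bad$start <- 5L
  expect_error(extract_cleavage_sites(bad, prot), "not found at stated start")
})

test_that("extraction deduplicates and is order-independent", {
  prot <- c(P1 = "MAIRGDSDGVDKAAAA")
  ev <- data.frame(replicate = c("r1", "r1", "r2"),
                   peptide = c("SDGVDK", "SDGVDK", "SDGVDK"),
                   accession = "P1", stringsAsFactors = FALSE)
  out <- extract_cleavage_sites(ev, prot)
  expect_equal(nrow(out), 2)  # same site in r1 deduplicated, r2 kept
  shuffled <- extract_cleavage_sites(ev[c(3, 1, 2), ], prot)
  expect_equal(out, shuffled)
})

test_that("family duplicates merge within replicate to the smallest accession", {
  ev <- make_events(c("r1", "r1"), c("PB", "PA"),
                    c("IRGDSDGV", "IRGDSDGV"), c(6, 9))
  out <- collapse_family_duplicates(ev)
  expect_equal(nrow(out), 1)
  expect_equal(out$accession, "PA")
  expect_equal(nrow(attr(out, "merge_log")), 1)
  # different replicates: both retained
  ev2 <- make_events(c("r1", "r2"), c("PB", "PA"),
                     c("IRGDSDGV", "IRGDSDGV"), c(6, 6))
  expect_equal(nrow(collapse_family_duplicates(ev2)), 2)
  # same accession, different sites with identical context: both retained
  ev3 <- make_events(c("r1", "r1"), c("PA", "PA"),
                     c("IRGDSDGV", "IRGDSDGV"), c(6, 40))
  expect_equal(nrow(collapse_family_duplicates(ev3)), 2)
  # toggled off: untouched
  expect_equal(nrow(collapse_family_duplicates(ev, collapse = FALSE)), 2)
})

test_that("wide site tables expand replicate indicators", {
  f <- write_tmp(c("accession\tcontext\trep1\trep2\trep3",
                   "P00001\tDEVDGSAK\t1\t0\t1",
                   "P00002\tAEVDGSAK\t0\t0\t0"))
  ev <- read_site_table(f)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$replicate, c("rep1", "rep3"))
  bad <- write_tmp(c("accession\tcontext\trep1",
                     "P00001\tAEVAGSAK\t1"))
  expect_error(read_site_table(bad), "row 1")
})

test_that("site tables round-trip through write and read", {
  prot <- c(P1 = "MAIRGDSDGVDKAAAA", P2 = "MKLVWDEVDGSAKLLL")
  evd <- data.frame(replicate = c("r1", "r2", "r1"),
                    peptide = c("SDGVDK", "SDGVDK", "GSAKLLL"),
                    accession = c("P1", "P1", "P2"),
                    stringsAsFactors = FALSE)
  ev <- extract_cleavage_sites(evd, prot)
  f <- tempfile(fileext = ".tsv")
  write_site_table(ev, f)
  back <- read_site_table(f)
  expect_equal(as.data.frame(ev), as.data.frame(back))
})

test_that("comma-delimited and gzipped tables are read transparently", {
  f <- tempfile(fileext = ".csv.gz")
  con <- gzfile(f, "wt")
  writeLines(c("replicate,peptide,accession", "r1,SDGVDK,P1"), con)
  close(con)
  ev <- read_evidence(f)
  expect_equal(ev$peptide, "SDGVDK")
  expect_error(read_evidence(write_tmp("peptide\tacc")), "replicate column")
})
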