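write_msa_fasta <- function(msa) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(msa)), msa)), f)
  f
}

write_clades_tsv <- function(clades) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tclade",
               paste(names(clades), unclass(clades), sep = "\t")), f)
  f
}

test_that("MSA and clade-table readers validate their inputs", {
  m <- make_synthetic_msa(c("all", "none"), n_chordata = 3, n_metazoa = 2,
                          n_eukaryota = 2, n_other = 2, seed = 1)
  msa <- read_msa(write_msa_fasta(m$msa))
  expect_equal(msa, m$msa)
  clades <- read_clade_table(write_clades_tsv(m$clades))
  expect_equal(unclass(clades), unclass(m$clades))

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD-", ">b", "ACD"), ragged)
  expect_error(read_msa(ragged), "ragged")

  short <- clade_table(unclass(m$clades)[-1])
  expect_error(conservation_fractions(m$msa, 1, short, "A"),
               "absent from clade table: REF")
  expect_error(clade_table(c(a = "bacteria")), "unknown clade label")
})

test_that("Stockholm alignments read identically to FASTA", {
  m <- make_synthetic_msa(c("all", "metazoa"), n_chordata = 3, n_metazoa = 2,
                          n_eukaryota = 2, n_other = 2, seed = 2)
  f <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               paste(names(m$msa), m$msa),
               "//"), f)
  expect_equal(read_msa(f), read_msa(write_msa_fasta(m$msa)))
})

test_that("reference positions resolve to the correct alignment column", {
  msa <- c(REF = "AC--DE", other = "ACGGDE")
  expect_equal(column_for_reference_position(msa, "REF", 3), 5)
  expect_equal(column_for_reference_position(msa, "REF", 1), 1)
  expect_error(column_for_reference_position(msa, "REF", 5), "outside")
  expect_error(column_for_reference_position(msa, "nope", 1), "not in MSA")

  # ungapped reference: column == position
  msa2 <- c(REF = "ACDEFG", o = "ACDEFG")
  expect_equal(column_for_reference_position(msa2, "REF", 5), 5)

  set.seed(7)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    row <- paste(sample(c("A", "C", "G", "-"), n, TRUE, prob = c(3, 3, 3, 2)),
                 collapse = "")
    if (!grepl("[ACG]", row)) next
    npos <- nchar(gsub("-", "", row))
    pos <- sample(npos, 1)
    msa_i <- c(REF = row)
    expect_equal(column_for_reference_position(msa_i, "REF", pos),
                 oracle_ref_column(row, pos))
  }
})

test_that("per-clade fractions are cumulative and count gaps as mismatches", {
  # 25/25/25/25 rows per innermost label; metazoa cumulative = 50 rows with
  # 48 matches (0.96), eukaryota cumulative = 75 rows with 37.5 -> use 75
  # rows and 37 extra mismatches to land exactly on 0.50 via counts
  n <- c(chordata = 25, metazoa = 25, eukaryota = 50, other = 100)
  labels <- rep(names(n), n)
  ids <- sprintf("s%03d", seq_len(sum(n)))
  col <- rep("W", sum(n))
  # metazoa cumulative: 50 rows, 48 carry W -> 0.96
  col[c(1, 2)] <- "V"
  # eukaryota cumulative: 100 rows, want 50 matches -> 48 already, add 2,
  # i.e. 48 of the 50 innermost-eukaryota rows mismatch
  col[51:98] <- "V"
  # all: keep every outer row mismatching
  col[101:200] <- c(rep("V", 50), rep("-", 50)) # gaps count as mismatches
  msa <- stats::setNames(col, ids)
  clades <- clade_table(stats::setNames(labels, ids))
  fr <- conservation_fractions(msa, 1, clades, "W")
  expect_equal(unname(fr),
               c(23 / 25, 48 / 50, 50 / 100, 50 / 200))

  # identical column
  msa1 <- stats::setNames(rep("K", 10), sprintf("t%d", 1:10))
  cl1 <- clade_table(stats::setNames(rep(c("chordata", "other"), 5),
                                     names(msa1)))
  expect_equal(unname(conservation_fractions(msa1, 1, cl1, "K")),
               rep(1, 4))
  # residue unique to the reference in a 20-row MSA
  msa2 <- stats::setNames(c("R", rep("Q", 19)), sprintf("u%d", 1:20))
  cl2 <- clade_table(stats::setNames(rep("other", 20), names(msa2)))
  fr2 <- conservation_fractions(msa2, 1, cl2, "R")
  expect_true(is.na(fr2[["chordata"]])) # empty clade: not evaluable
  expect_lte(fr2[["all"]], 0.05)
})

test_that("the call is the most general clade above the threshold", {
  cfg <- conservation_config()
  f <- function(ch, me, eu, al) c(chordata = ch, metazoa = me,
                                  eukaryota = eu, all = al)
  expect_equal(classify_conservation(f(1, 1, 1, 1), cfg), "all")
  expect_equal(classify_conservation(f(0.99, 0.96, 0.80, 0.60), cfg), "metazoa")
  expect_equal(classify_conservation(f(0.95, 0.95, 0.95, 0.95), cfg), "none")
  expect_equal(classify_conservation(f(0.99, 0.3, 0.3, 0.2), cfg), "chordata")
  expect_equal(classify_conservation(f(NA, NA, NA, 0.99), cfg), "all")
  expect_equal(classify_conservation(f(NA, 0.99, 0.5, 0.5), cfg), "metazoa")
})

test_that("raising the threshold never broadens a call", {
  order_ <- c(none = 0, chordata = 1, metazoa = 2, eukaryota = 3, all = 4)
  set.seed(13)
  for (i in 1:100) {
    fr <- sort(runif(4), decreasing = TRUE) # nested fractions are monotone
    names(fr) <- c("chordata", "metazoa", "eukaryota", "all")[1:4]
    fr <- fr[c("chordata", "metazoa", "eukaryota", "all")]
    calls <- vapply(c(0.5, 0.7, 0.9, 0.97),
                    function(th) classify_conservation(fr, conservation_config(th)),
                    character(1))
    expect_true(all(diff(order_[calls]) <= 0))
  }
})
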