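# Readers and writers for FASTA, CT, dot-bracket, ss-count, siRNA tables
# and the feature table.

test_that("read_fasta normalizes the alphabet and preserves order", {
    f <- tmp_file(c(">x", "ACGT"), ".fasta")
    rec <- read_fasta(f)
    expect_equal(rec$id, "x")
    expect_equal(rec$sequence, "ACGU")
    expect_equal(rec$length, 4L)

    f2 <- tmp_file(c(">a", "AC", "GU", ">b", "GGG"), ".fasta")
    rec2 <- read_fasta(f2)
    expect_equal(rec2$id, c("a", "b"))
    expect_equal(rec2$length, c(4L, 3L))

    f3 <- tmp_file(c(">a desc here", "ACGU"), ".fasta")
    expect_equal(read_fasta(f3)$id, "a")
})

test_that("read_fasta rejects degenerate and non-IUPAC input", {
    expect_error(read_fasta(tmp_file(c(">a", ""), ".fasta")), "empty sequence")
    expect_error(read_fasta(tmp_file(c(">a", "ACGN"), ".fasta")), "'N'")
    expect_error(read_fasta(tmp_file(c(">a", "ACGX"), ".fasta")), "non-IUPAC")
    expect_error(read_fasta(tempfile()), "not found")
})

test_that("secondary_structure enforces its invariants", {
    expect_silent(secondary_structure("GGGAAACCC",
                                      c(9, 8, 7, 0, 0, 0, 3, 2, 1)))
    # involution violation
    expect_error(secondary_structure("GGGAAACCC",
                                     c(9, 0, 0, 0, 0, 0, 0, 0, 0)),
                 "involution")
    # self pair
    expect_error(secondary_structure("GGGAAACCC",
                                     c(0, 0, 0, 4, 0, 0, 0, 0, 0)),
                 "self-pair")
    # pseudoknot: 1-5 crossing 3-8
    expect_error(secondary_structure("GAGAACUCU",
                                     c(5, 0, 8, 0, 1, 0, 0, 3, 0)),
                 "pseudoknot")
    # hairpin too short
    expect_error(secondary_structure("GAAC", c(4, 0, 0, 1)), "hairpin")
    # illegal pair (A-G)
    expect_error(secondary_structure("AAAAAGGGG", c(9, 0, 0, 0, 0, 0, 0, 0, 1)),
                 "illegal pair")
})

test_that("read_ct parses open chains, pairs and energies", {
    f <- tmp_file(c("4",
                    "1 G 0 2 0 1", "2 A 1 3 0 2", "3 A 2 4 0 3",
                    "4 C 3 0 0 4"), ".ct")
    s <- read_ct(f)
    expect_equal(s$pairs, rep(0L, 4))
    expect_equal(s$sequence, "GAAC")

    rows <- c("1 G 0 2 9 1", "2 G 1 3 8 2", "3 G 2 4 7 3",
              "4 A 3 5 0 4", "5 A 4 6 0 5", "6 A 5 7 0 6",
              "7 C 6 8 3 7", "8 C 7 9 2 8", "9 C 8 0 1 9")
    s2 <- read_ct(tmp_file(c("9 dG = -9.0", rows), ".ct"))
    expect_equal(s2$pairs[1:3], c(9L, 8L, 7L))
    expect_equal(sum(s2$pairs > 0), 6)
    expect_equal(s2$energy, -9)

    # bare-real energy header and trailing columns tolerated
    s3 <- read_ct(tmp_file(c("4 -1.5",
                             "1 G 0 2 0 1 7", "2 A 1 3 0 2 8",
                             "3 A 2 4 0 3 9", "4 C 3 0 0 4 10"), ".ct"))
    expect_equal(s3$energy, -1.5)
})

test_that("read_ct names the offending row on corrupted input", {
    f <- tmp_file(c("5",
                    "1 G 0 2 5 1", "2 A 1 3 0 2", "3 A 2 4 0 3",
                    "4 A 3 5 0 4", "5 C 4 0 0 5"), ".ct")
    expect_error(read_ct(f), "row 1.*5|involution")
    expect_error(read_ct(tmp_file(c("3", "1 G 0 2 0 1", "2 A 1 3 0 2"), ".ct")),
                 "2 rows.*3")
})

test_that("CT round-trip preserves the pair table exactly", {
    set.seed(101)
    for (r in 1:10) {
        s <- fold_optimal(rand_rna(sample(8:25, 1)))
        f <- tempfile(fileext = ".ct")
        write_ct(s, f)
        s2 <- read_ct(f)
        expect_identical(s2$pairs, s$pairs)
        expect_equal(s2$energy, s$energy)
        expect_equal(s2$sequence, s$sequence)
    }
})

test_that("read_dotbracket matches brackets and validates", {
    s <- read_dotbracket("GGGAAACCC", "(((...)))")
    expect_equal(s$pairs, c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
    expect_equal(read_dotbracket("ACGU", "....")$pairs, rep(0L, 4))
    expect_error(read_dotbracket("GGGAACCC", "(((..)))"), "hairpin")
    expect_error(read_dotbracket("GGGAAACCC", "(((...))"), "lengths differ")
    expect_error(read_dotbracket("GGGAAACC", "(((...))"), "unbalanced")
    expect_error(read_dotbracket("AGGAAACCG", "(((...)))"), "illegal pair")
})

test_that("dot-bracket and CT agree on the same structure", {
    set.seed(202)
    for (r in 1:5) {
        s <- fold_optimal(rand_rna(sample(10:30, 1)))
        f <- tempfile(fileext = ".ct")
        write_ct(s, f)
        expect_identical(read_ct(f)$pairs,
                         read_dotbracket(s$sequence, as_dotbracket(s))$pairs)
    }
})

test_that("read_ss_count parses the Mfold dialect and checks bounds", {
    ss <- read_ss_count(tmp_file(c("2", "1 2", "2 0", "3 1")))
    expect_equal(ss$counts, c(2L, 0L, 1L))
    expect_equal(ss$n_structures, 2L)
    expect_error(read_ss_count(tmp_file(c("2", "1 5", "2 0"))), "outside 0..2")
    expect_error(read_ss_count(tmp_file(c("2", "1 1", "3 1"))),
                 "missing position 2")
})

test_that("efficacy classes follow the VH/H/M/L cut-offs", {
    expect_equal(efficacy_class_from_percent(c(95, 90, 89.9, 70, 69.9,
                                               50, 49.9, 0, 100)),
                 c("VH", "VH", "H", "H", "M", "M", "L", "L", "VH"))
    expect_error(efficacy_class_from_percent(101), "0,100")
})

test_that("read_sirna_table derives classes and validates guides", {
    f <- tmp_file(c("id\tguide\ttarget_id\tefficacy",
                    "s1\tACGUACGUACGUACGUACG\tm1\t95",
                    "s2\tacguacguacguacguacgua\tm1\t50",
                    "s3\tACGUACGUACGUACGUACG\tm2\tVH"))
    tab <- read_sirna_table(f)
    expect_equal(tab$efficacy_class, c("VH", "M", "VH"))
    expect_equal(tab$guide[2], "ACGUACGUACGUACGUACGUA")
    expect_true(is.na(tab$efficacy_percent[3]))

    expect_error(read_sirna_table(
        tmp_file(c("id\tguide\ttarget_id\tefficacy",
                   "s1\tACGUACGUACGUACGUAC\tm1\t95"))), "guide length")
    expect_error(read_sirna_table(
        tmp_file(c("id\tguide\ttarget_id\tefficacy",
                   "s1\tACGUACGUACGUACGUACG\tm1\tgreat"))),
        "unknown efficacy token")
    # CSV autodetection
    fc <- tmp_file(c("id,guide,target_id,efficacy",
                     "s1,ACGUACGUACGUACGUACG,m1,20"), ".csv")
    expect_equal(read_sirna_table(fc)$efficacy_class, "L")
})

test_that("feature table writing is deterministic and round-trips", {
    expect_equal(readLines(write_feature_table(data.frame(),
                                               tempfile(fileext = ".tsv"))),
                 paste(siRNAtarget:::FEATURE_COLUMNS, collapse = "\t"))

    fx <- fixture_study()
    feats <- compute_features(fx$mrnas, fx$sirnas, ensemble_k = 5)
    f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
    write_feature_table(feats, f1)
    back <- read_feature_table(f1)
    expect_equal(nrow(back), nrow(feats))
    expect_equal(back$n_unpaired, feats$n_unpaired)
    expect_equal(back$hb_index, round(feats$hb_index, 4))
    expect_identical(back$runs, feats$runs)
    write_feature_table(back, f2)
    expect_identical(readLines(f1), readLines(f2))
})
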