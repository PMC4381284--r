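# Element classification of nested structures: hand-walked examples,
# partition and mirror invariants, and agreement with the recursive
# loop-walk oracle.

lab_of <- function(seq, db) annotate(read_dotbracket(seq, db))$labels

test_that("annotate reproduces hand-walked loop decompositions", {
    # plain hairpin
    l1 <- lab_of("GGGAAACCC", "(((...)))")
    expect_equal(l1[4:6], rep("h_loop", 3))
    expect_equal(l1[c(1:3, 7:9)], rep("stem", 6))

    # internal loop on both sides of the inner helix
    l2 <- lab_of("GGAAGGAAACCAACC", "((..((...))..))")
    expect_equal(l2[c(3, 4, 12, 13)], rep("int_loop", 4))
    expect_equal(l2[7:9], rep("h_loop", 3))
    expect_equal(l2[c(1, 2, 5, 6, 10, 11, 14, 15)], rep("stem", 8))

    # one-base bulge
    l3 <- lab_of("GGAGGAAACCCC", "((.((...))))")
    expect_equal(l3[3], "one_bb")
    expect_equal(l3[6:8], rep("h_loop", 3))
    expect_equal(l3[c(1, 2, 4, 5, 9:12)], rep("stem", 8))

    # no pairs at all -> everything is the 5' exterior tail
    expect_equal(lab_of("ACGU", "...."), rep("loop5", 4))

    # two-or-longer one-sided bulge
    l4 <- lab_of("GGAAGGAAACCCC", "((..((...))))")
    expect_equal(l4[3:4], rep("b_loop", 2))

    # multibranch: two helices under an outer pair
    l5 <- lab_of("GGGGAGGCGAAAGCCAAGGCGAAAGCCACCCC",
                 "((((.(((....)))..(((....))).))))")
    expect_equal(l5[c(5, 16, 17, 28)], rep("mb_loop", 4))

    # exterior tails and the split of an inter-helix exterior segment
    l6 <- lab_of("AAGGGAAACCCAAAGGGAAACCCAA",
                 "..(((...)))...(((...)))..")
    expect_equal(l6[1:2], rep("loop5", 2))
    expect_equal(l6[24:25], rep("loop3", 2))
    # middle segment 12..14: one 5' position -> loop3, rest -> loop5
    expect_equal(l6[12:14], c("loop3", "loop5", "loop5"))
})

test_that("labels partition every structure (paired <=> stem)", {
    set.seed(401)
    for (r in 1:20) {
        s <- fold_optimal(rand_rna(sample(10:40, 1)))
        ann <- annotate(s)
        expect_equal(length(ann$labels), nchar(s$sequence))
        expect_true(all(ann$labels %in% ALL_CLASSES))
        expect_equal(ann$labels == "stem", s$pairs > 0)
    }
})

test_that("element_counts_in_site sums to the window length", {
    ann <- annotate(read_dotbracket("GGGAAACCC", "(((...)))"))
    c1 <- element_counts_in_site(ann, c(4, 6))
    expect_equal(unname(c1["h_loop"]), 3L)
    expect_equal(sum(c1), 3L)
    c2 <- element_counts_in_site(ann, c(1, 9))
    expect_equal(unname(c2[c("stem", "h_loop")]), c(6L, 3L))
    # single position: exactly one count of 1
    c3 <- element_counts_in_site(ann, c(5, 5))
    expect_equal(sum(c3), 1L)
    expect_equal(sum(c3 > 0), 1L)
    expect_error(element_counts_in_site(ann, c(0, 5)), "out of range")
    expect_error(element_counts_in_site(ann, c(5, 10)), "out of range")
})

test_that("random windows preserve the partition and the stem recount", {
    set.seed(402)
    for (r in 1:50) {
        s <- fold_optimal(rand_rna(sample(12:50, 1)))
        n <- nchar(s$sequence)
        a <- sample(n, 1); b <- a + sample.int(n - a + 1, 1) - 1L
        counts <- element_counts_in_site(annotate(s), c(a, b))
        expect_equal(sum(counts), b - a + 1L)
        expect_equal(unname(counts["stem"]), sum(s$pairs[a:b] > 0))
    }
})

test_that("annotate agrees with the recursive loop-walk oracle", {
    set.seed(403)
    for (r in 1:30) {
        seq <- rand_rna(sample(5:12, 1))
        for (p in oracle_enumerate(seq)) {
            s <- secondary_structure(seq, p)
            expect_equal(annotate(s)$labels, oracle_annotate(p),
                         info = paste(seq, paste(p, collapse = ",")))
        }
    }
})

test_that("reversing the molecule swaps the 5' and 3' exterior labels", {
    mirror <- function(s) {
        n <- nchar(s$sequence)
        p <- s$pairs
        pm <- rev(ifelse(p > 0, n + 1L - p, 0L))
        seqm <- paste(rev(strsplit(s$sequence, "")[[1]]), collapse = "")
        secondary_structure(seqm, pm)
    }
    swap <- c(loop5 = "loop3", loop3 = "loop5", int_loop = "int_loop",
              mb_loop = "mb_loop", h_loop = "h_loop", b_loop = "b_loop",
              one_bb = "one_bb", stem = "stem")
    set.seed(404)
    done <- 0
    for (r in 1:40) {
        s <- fold_optimal(rand_rna(sample(10:30, 1)))
        labs <- annotate(s)$labels
        labs_m <- annotate(mirror(s))$labels
        # the inter-helix exterior split is deliberately 5'/3' asymmetric at
        # odd middles; skip structures with odd inter-helix segments
        p <- s$pairs
        ext <- which(p == 0 & labs %in% c("loop5", "loop3"))
        paired <- which(p > 0)
        if (length(paired)) {
            midseg <- ext[ext > min(paired) & ext < max(paired)]
            if (length(midseg) %% 2 == 1) next
            if (length(midseg)) {
                segs <- split(midseg, cumsum(c(1, diff(midseg) != 1)))
                if (any(vapply(segs, length, 1L) %% 2 == 1)) next
            }
        }
        expect_equal(labs_m, unname(rev(swap[labs])))
        done <- done + 1
    }
    expect_gte(done, 10)
})

test_that("instance counting collapses each loop and helix to one unit", {
    # internal loop (both sides) + hairpin under a two-helix stack
    ann <- annotate(read_dotbracket("GGAAGGAAACCAACC", "((..((...))..))"))
    inst <- element_instances_in_site(ann, c(1, 15))
    base <- element_counts_in_site(ann, c(1, 15))
    # 4 int-loop bases but a single internal loop; 2 helices; 1 hairpin
    expect_equal(unname(base[["int_loop"]]), 4L)
    expect_equal(unname(inst[["int_loop"]]), 1L)
    expect_equal(unname(inst[["stem"]]), 2L)
    expect_equal(unname(inst[["h_loop"]]), 1L)
    # multibranch: both unpaired segments belong to one loop instance
    ann2 <- annotate(read_dotbracket("GGGGAGGCGAAAGCCAAGGCGAAAGCCACCCC",
                                     "((((.(((....)))..(((....))).))))"))
    inst2 <- element_instances_in_site(ann2, c(1, 32))
    expect_equal(unname(inst2[["mb_loop"]]), 1L)
    expect_equal(unname(inst2[["stem"]]), 3L)
    # a window touching only part of a loop still counts one instance
    expect_equal(unname(element_instances_in_site(ann, c(3, 4))[["int_loop"]]),
                 1L)
    # instance counts never exceed base counts
    set.seed(405)
    for (r in 1:10) {
        s <- fold_optimal(rand_rna(sample(15:40, 1)))
        n <- nchar(s$sequence)
        a <- sample(n, 1); b <- a + sample.int(n - a + 1, 1) - 1L
        expect_true(all(element_instances_in_site(annotate(s), c(a, b)) <=
                        element_counts_in_site(annotate(s), c(a, b))))
    }
})

test_that("annotation serializes as TSV and as a compact string", {
    ann <- annotate(read_dotbracket("GGGAAACCC", "(((...)))"))
    expect_equal(annotation_string(ann), "SSSHHHSSS")
    f <- tempfile(fileext = ".tsv")
    write_annotation(ann, f)
    back <- read.delim(f)
    expect_equal(back$label, ann$labels)
    expect_equal(back$position, 1:9)
})
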