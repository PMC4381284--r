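# Thermodynamic and composition features: nearest-neighbour duplex energy,
# opening costs, the net binding energy and GC binning.

test_that("gc_percent is the G+C fraction in percent", {
    expect_equal(gc_percent("GCGC"), 100)
    expect_equal(gc_percent("AUAU"), 0)
    expect_equal(gc_percent(paste0(strrep("G", 9), strrep("A", 10))),
                 100 * 9 / 19)
    expect_error(gc_percent(""), "empty")
})

test_that("gc_bin assigns the study's main bins and subgroups", {
    b <- gc_bin(c(47.4, 60, 20))
    expect_equal(b$main, c("25-55%", ">55%", "<25%"))
    expect_equal(b$subgroup, c("45-54%", "55-64%", NA))
    # boundary handling: [25,55] closed; subgroups half-open decades
    b2 <- gc_bin(c(25, 55, 65, 24.99, 34.99, 35))
    expect_equal(b2$main, c("25-55%", "25-55%", ">55%", "<25%",
                            "25-55%", "25-55%"))
    expect_equal(b2$subgroup, c("25-34%", "55-64%", NA, NA,
                                "25-34%", "35-44%"))
})

test_that("main GC bins partition [0,100] on a dense grid", {
    g <- seq(0, 100, by = 0.25)
    b <- gc_bin(g)
    expect_true(all(!is.na(b$main)))
    expect_true(all(c("<25%", "25-55%", ">55%") %in% b$main))
    expect_error(gc_bin(101), "0,100")
})

test_that("dg_duplex sums stacks with initiation and terminal penalties", {
    nn <- default_nn_params()
    # homopolymeric stack: length-linear with both AU terminals
    for (n in c(5, 10, 19)) {
        top <- strrep("A", n)
        expect_equal(dg_duplex(rna_revcomp(top), top),
                     (n - 1) * nn$stack[["AA/UU"]] + nn$init +
                         2 * nn$terminal_au)
    }
    # hand sum against the packaged table: GCGC has stacks GC, CG, GC
    expect_equal(dg_duplex("GCGC", "GCGC"),
                 2 * nn$stack[["GC/CG"]] + nn$stack[["CG/GC"]] + nn$init)
    expect_equal(dg_duplex("GCGC", "GCGC"), -5.11)
    # rotational symmetry: the duplex read from the other strand (both
    # strands reversed, i.e. the 180-degree rotation) has the same energy
    set.seed(601)
    for (r in 1:10) {
        top <- rand_rna(sample(5:21, 1))
        guide <- rna_revcomp(top)
        expect_equal(dg_duplex(guide, top), dg_duplex(top, guide))
    }
    expect_error(dg_duplex("GCGC", "GGGG"), "reverse complement")
    expect_error(dg_duplex("G", "C"), "at least 2")
})

test_that("dg_duplex is additive over a concatenation joint", {
    nn <- default_nn_params()
    a <- "GGCA"; b <- "CUGC"
    joint_key <- paste0(substr(a, 4, 4), substr(b, 1, 1))
    joint_key <- paste0(joint_key, "/",
                        chartr("ACGU", "UGCA", substr(joint_key, 1, 1)),
                        chartr("ACGU", "UGCA", substr(joint_key, 2, 2)))
    e_ab <- dg_duplex(rna_revcomp(paste0(a, b)), paste0(a, b))
    e_a <- dg_duplex(rna_revcomp(a), a)
    e_b <- dg_duplex(rna_revcomp(b), b)
    terminal <- function(x) {
        ends <- c(substr(x, 1, 1), substr(x, nchar(x), nchar(x)))
        sum(ends %in% c("A", "U")) * nn$terminal_au
    }
    expect_equal(e_ab,
                 e_a + e_b + nn$stack[[joint_key]] - nn$init -
                     terminal(a) - terminal(b) + terminal(paste0(a, b)))
})

test_that("dg_break_target is the optimal-minus-constrained score gap", {
    # site already unpaired in the optimal fold -> 0
    seq <- paste0("GGGGGAAAACCCCC", strrep("A", 10))
    expect_equal(dg_break_target(seq, fold_optimal(seq), c(15, 24)), 0)
    # forcing a fully paired stem open costs strictly
    expect_lt(dg_break_target("GGGGGAAAACCCCC",
                              fold_optimal("GGGGGAAAACCCCC"), c(1, 5)), 0)
    # toy 9-mer against the two brute-force folds
    seq9 <- "GGGAAACCC"
    wts <- function(keep) {
        ps <- Filter(keep, oracle_enumerate(seq9))
        max(vapply(ps, function(p) oracle_structure_weight(seq9, p),
                   numeric(1)))
    }
    w_all <- wts(function(p) TRUE)
    w_con <- wts(function(p) all(p[1:3] == 0))
    expect_equal(dg_break_target(seq9, fold_optimal(seq9), c(1, 3)),
                 (-w_all) - (-w_con))
})

test_that("dg_break_target grows (more negative) with the site", {
    set.seed(602)
    for (r in 1:10) {
        seq <- rand_rna(30)
        opt <- fold_optimal(seq)
        d1 <- dg_break_target(seq, opt, c(5, 10))
        d2 <- dg_break_target(seq, opt, c(5, 20))
        expect_lte(d2, d1)
        expect_lte(d1, 0)
    }
})

test_that("dg_oligo_self is the guide's own fold stability", {
    expect_equal(dg_oligo_self(strrep("A", 19)), 0)
    expect_lt(dg_oligo_self("GGGGGAAAACCCCCAAAAA"), 0)
    set.seed(603)
    for (r in 1:10) {
        g <- rand_rna(19)
        best <- max(vapply(oracle_enumerate(substr(g, 1, 12)), function(p)
            oracle_structure_weight(substr(g, 1, 12), p), numeric(1)))
        expect_equal(dg_oligo_self(substr(g, 1, 12)), -best)
    }
})

test_that("dg_overall composes the three terms with sign checks", {
    expect_equal(dg_overall(-35, 0, 0), -35)
    expect_equal(dg_overall(-35.57, -14.56, 0), -21.01)
    expect_equal(dg_overall(-30, -10, -2), -18)
    expect_error(dg_overall(-30, 5, 0), "<= 0")
    expect_error(dg_overall(-30, 0, 1), "<= 0")
})

test_that("net binding is never stronger than the duplex term", {
    set.seed(604)
    for (r in 1:50) {
        seq <- rand_rna(40)
        start <- sample(1:(40 - 18), 1)
        site <- c(start, start + 18L)
        guide <- rna_revcomp(substr(seq, site[1], site[2]))
        d <- dg_duplex(guide, substr(seq, site[1], site[2]))
        b <- dg_break_target(seq, fold_optimal(seq), site)
        s <- dg_oligo_self(guide)
        expect_gte(dg_overall(d, b, s), d)
    }
})

test_that("nn parameter files are validated and re-readable", {
    nn <- default_nn_params()
    expect_equal(nn$source_tag, "xia1998-wc-37C")
    expect_length(nn$stack, 16)
    # rotational consistency of the packaged table
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    for (key in names(nn$stack)) {
        b <- strsplit(sub("/.*", "", key), "")[[1]]
        rot <- paste0(comp[b[2]], comp[b[1]], "/", b[2], b[1])
        expect_equal(nn$stack[[key]], nn$stack[[rot]])
    }
    # missing stack rejected
    f <- tempfile(fileext = ".tsv")
    df <- data.frame(key = c("AA/UU", "init", "terminal_au"),
                     energy = c(-0.93, 4.09, 0.45))
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(read_nn_params(f), "missing stack")
})
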