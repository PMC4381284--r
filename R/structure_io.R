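# I/O for every external format the pipeline touches: FASTA, CT connect
# files, Vienna dot-bracket, Mfold-style ss-count files, delimited siRNA
# tables and the TSV feature table.  All coordinates 1-based, inclusive.

#' Construct and validate a secondary structure
#'
#' A nested (pseudoknot-free) secondary structure: an RNA sequence plus a
#' pair table \code{pairs} with \code{pairs[i] = j} when i pairs j and 0 when
#' i is unpaired.  Validation enforces involution, no self pairs,
#' nestedness, the minimum hairpin span of 3 unpaired nucleotides, and pair
#' legality (Watson-Crick plus GU wobble).
#'
#' @param sequence RNA string (T is normalized to U).
#' @param pairs integer pair table, 1-based, 0 = unpaired.
#' @param energy optional score/energy (more negative = more stable).
#' @return an object of class \code{secondary_structure}.
#' @export
secondary_structure <- function(sequence, pairs, energy = NA_real_) {
    validate_secondary_structure(sequence, pairs, energy)
}

# fast path for structures produced by the engine, which are valid by
# construction (covered by the property tests); skips the O(n) validator
new_secondary_structure <- function(sequence, pairs, energy = NA_real_) {
    structure(list(sequence = sequence, pairs = as.integer(pairs),
                   energy = as.numeric(energy)[1L]),
              class = "secondary_structure")
}

validate_secondary_structure <- function(sequence, pairs, energy = NA_real_) {
    sequence <- normalize_rna(sequence)
    n <- nchar(sequence)
    pairs <- as.integer(pairs)
    if (length(pairs) != n)
        stop("pair table length (", length(pairs),
             ") does not match sequence length (", n, ")")
    if (any(pairs < 0L | pairs > n))
        stop("pair table entries must lie in 0..", n)
    idx <- which(pairs > 0L)
    for (i in idx) {
        j <- pairs[i]
        if (j == i) stop("self-pair at position ", i)
        if (pairs[j] != i)
            stop("pair table is not an involution: positions ", i, " and ", j)
    }
    # nestedness via stack matching
    stack <- integer(0)
    for (i in seq_len(n)) {
        j <- pairs[i]
        if (j > i) {
            stack <- c(stack, i)
        } else if (j > 0L && j < i) {
            if (!length(stack) || stack[length(stack)] != j)
                stop("pseudoknot detected at pair ", j, "-", i)
            stack <- stack[-length(stack)]
        }
    }
    # hairpin span and pair legality
    bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
    legal <- c("AU", "UA", "GC", "CG", "GU", "UG")
    for (i in idx[pairs[idx] > idx]) {
        j <- pairs[i]
        if (!(paste0(bases[i], bases[j]) %in% legal))
            stop("illegal pair ", bases[i], "-", bases[j],
                 " at positions ", i, "-", j)
        inner <- if (j - i > 1L) pairs[(i + 1L):(j - 1L)] else integer(0)
        if (!any(inner > 0L) && (j - i - 1L) < 3L)
            stop("hairpin loop of ", j - i - 1L, " < 3 closed by pair ",
                 i, "-", j)
    }
    structure(list(sequence = sequence, pairs = pairs,
                   energy = as.numeric(energy)[1L]),
              class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
    cat("secondary_structure, length", nchar(x$sequence), "nt,",
        sum(x$pairs > 0) / 2, "pairs")
    if (!is.na(x$energy)) cat(", score", format(x$energy))
    cat("\n", x$sequence, "\n ", as_dotbracket(x), "\n", sep = "")
    invisible(x)
}

#' Dot-bracket string of a nested structure
#' @param structure a \code{secondary_structure}.
#' @return character scalar over \code{. ( )}.
#' @export
as_dotbracket <- function(structure) {
    p <- structure$pairs
    db <- rep(".", length(p))
    db[p > seq_along(p)] <- "("
    db[p > 0 & p < seq_along(p)] <- ")"
    paste(db, collapse = "")
}

#' Read a multi-record FASTA file of mRNA sequences
#'
#' Parsing is delegated to \pkg{Biostrings}; sequences are then normalized
#' to the RNA alphabet (T/t to U) and validated.  Record ids are the header
#' up to the first whitespace; input order is preserved.
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{id}, \code{sequence}, \code{length}.
#' @export
read_fasta <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
    out <- vector("list", length(set))
    for (k in seq_along(seqs)) {
        if (!nzchar(seqs[k]))
            stop("empty sequence for record '", ids[k], "'")
        out[[k]] <- normalize_rna(seqs[k], what = paste0("record '", ids[k], "'"))
    }
    data.frame(id = ids, sequence = unlist(out),
               length = nchar(unlist(out)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a CT ("connect") secondary-structure file
#'
#' Dialect: a header line whose first token is the sequence length,
#' optionally carrying an energy as \code{dG = x} or a bare real; then one
#' row per nucleotide \code{i base i-1 i+1 j i}.  Trailing columns beyond
#' the canonical six are ignored.  The resulting pair table is validated
#' against all structure invariants.
#'
#' @param path CT file.
#' @return a \code{secondary_structure}.
#' @export
read_ct <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty CT file: ", path)
    htok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    n <- suppressWarnings(as.integer(htok[1]))
    if (is.na(n) || n < 1L) stop("CT header does not start with a length")
    energy <- NA_real_
    m <- regmatches(lines[1], regexpr("dG\\s*=\\s*(-?[0-9.]+)", lines[1]))
    if (length(m)) {
        energy <- as.numeric(sub("dG\\s*=\\s*", "", m))
    } else if (length(htok) >= 2) {
        v <- suppressWarnings(as.numeric(htok[2]))
        if (!is.na(v)) energy <- v
    }
    if (length(lines) - 1L != n)
        stop("CT body has ", length(lines) - 1L, " rows, header says ", n)
    bases <- character(n)
    pairs <- integer(n)
    for (r in seq_len(n)) {
        tok <- strsplit(trimws(lines[r + 1L]), "\\s+")[[1]]
        if (length(tok) < 6L) stop("CT row ", r, " has fewer than 6 columns")
        i <- as.integer(tok[1])
        if (is.na(i) || i != r) stop("CT row ", r, " is numbered ", tok[1])
        bases[r] <- tok[2]
        j <- suppressWarnings(as.integer(tok[5]))
        if (is.na(j) || j < 0L || j > n)
            stop("CT row ", r, " has invalid partner '", tok[5], "'")
        pairs[r] <- j
    }
    # name the offending row explicitly before full validation
    for (r in which(pairs > 0L)) {
        if (pairs[pairs[r]] != r)
            stop("CT involution violation: row ", r, " points to ", pairs[r],
                 " but row ", pairs[r], " points to ", pairs[pairs[r]])
    }
    secondary_structure(paste(bases, collapse = ""), pairs, energy)
}

#' Write a secondary structure as a CT file
#' @param structure a \code{secondary_structure}.
#' @param path output file.
#' @export
write_ct <- function(structure, path) {
    n <- nchar(structure$sequence)
    bases <- strsplit(structure$sequence, "", fixed = TRUE)[[1]]
    header <- if (is.na(structure$energy)) as.character(n)
              else sprintf("%d dG = %.4f", n, structure$energy)
    rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                    seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                    structure$pairs, seq_len(n))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Parse a Vienna dot-bracket string into a secondary structure
#'
#' @param seq RNA string (same length as \code{db}).
#' @param db string over \code{. ( )}.
#' @return a \code{secondary_structure}.
#' @export
read_dotbracket <- function(seq, db) {
    seq <- normalize_rna(seq)
    if (nchar(seq) != nchar(db))
        stop("sequence and dot-bracket lengths differ (",
             nchar(seq), " vs ", nchar(db), ")")
    sym <- strsplit(db, "", fixed = TRUE)[[1]]
    if (length(bad <- setdiff(unique(sym), c(".", "(", ")"))))
        stop("dot-bracket contains illegal characters: ",
             paste(bad, collapse = ", "))
    pairs <- integer(length(sym))
    stack <- integer(0)
    for (i in seq_along(sym)) {
        if (sym[i] == "(") {
            stack <- c(stack, i)
        } else if (sym[i] == ")") {
            if (!length(stack)) stop("unbalanced ')' at position ", i)
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pairs[i] <- j
            pairs[j] <- i
        }
    }
    if (length(stack)) stop("unbalanced '(' at position ", stack[1])
    secondary_structure(seq, pairs)
}

#' Read an Mfold-style ss-count file
#'
#' First line: the number of structures N in the ensemble; following lines
#' \code{position count [base]}.  \code{counts[i]} is the number of ensemble
#' structures in which position i is single-stranded.
#'
#' @param path ss-count file.
#' @return list of class \code{ss_count} with \code{counts},
#'   \code{n_structures}.
#' @export
read_ss_count <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("ss-count file has no positions: ", path)
    N <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(N) || N < 1L)
        stop("first line must be the (positive) number of structures")
    pos <- integer(length(lines) - 1L)
    cnt <- integer(length(lines) - 1L)
    for (r in seq_along(pos)) {
        tok <- strsplit(trimws(lines[r + 1L]), "\\s+")[[1]]
        pos[r] <- as.integer(tok[1])
        cnt[r] <- as.integer(tok[2])
    }
    L <- max(pos)
    missing <- setdiff(seq_len(L), pos)
    if (length(missing))
        stop("missing position ", missing[1], " in ss-count file")
    counts <- integer(L)
    counts[pos] <- cnt
    if (any(counts < 0L | counts > N))
        stop("ss-count at position ", which(counts < 0L | counts > N)[1],
             " outside 0..", N)
    ss_count_vector(counts, N)
}

#' Construct an ss-count vector
#' @param counts integer vector of single-stranded counts per position.
#' @param n_structures ensemble size.
#' @return object of class \code{ss_count}.
#' @export
ss_count_vector <- function(counts, n_structures) {
    counts <- as.integer(counts)
    n_structures <- as.integer(n_structures)
    if (n_structures < 1L) stop("n_structures must be positive")
    if (any(counts < 0L | counts > n_structures))
        stop("counts must lie in 0..n_structures")
    structure(list(counts = counts, n_structures = n_structures),
              class = "ss_count")
}

#' Write an ss-count vector in the Mfold dialect
#' @param ss an \code{ss_count} object.
#' @param path output file.
#' @param sequence optional RNA string appended as a third column.
#' @export
write_ss_count <- function(ss, path, sequence = NULL) {
    body <- if (is.null(sequence)) {
        sprintf("%d %d", seq_along(ss$counts), ss$counts)
    } else {
        sprintf("%d %d %s", seq_along(ss$counts), ss$counts,
                strsplit(sequence, "", fixed = TRUE)[[1]])
    }
    writeLines(c(as.character(ss$n_structures), body), path)
    invisible(path)
}

#' Silencing-efficacy class from a knockdown percentage
#'
#' Classes VH (90-100\%), H (70-90\%), M (50-70\%), L (0-50\%); boundaries
#' are assigned to the upper class at 90 and the lower class elsewhere, so
#' the intervals are [90,100] VH, [70,90) H, [50,70) M, [0,50) L.
#'
#' @param percent numeric vector in [0,100].
#' @return character vector over \{VH,H,M,L\}.
#' @export
efficacy_class_from_percent <- function(percent) {
    if (any(!is.na(percent) & (percent < 0 | percent > 100)))
        stop("efficacy percent must lie in [0,100]")
    cls <- ifelse(percent >= 90, "VH",
           ifelse(percent >= 70, "H",
           ifelse(percent >= 50, "M", "L")))
    cls[is.na(percent)] <- NA_character_
    cls
}

#' Read a delimited siRNA table
#'
#' Expected columns (header required): \code{id}, \code{guide},
#' \code{target_id} and \code{efficacy} (a percentage or a class token in
#' \{VH,H,M,L\}).  TSV vs CSV is autodetected from the extension.  Guides
#' are normalized to the RNA alphabet and must be 19-21 nt.
#'
#' @param path table file.
#' @return data.frame with columns \code{id}, \code{guide},
#'   \code{target_id}, \code{efficacy_percent}, \code{efficacy_class}.
#' @export
read_sirna_table <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
    need <- c("id", "guide", "target_id", "efficacy")
    if (length(miss <- setdiff(need, names(df))))
        stop("siRNA table lacks column(s): ", paste(miss, collapse = ", "))
    if (!nrow(df)) stop("siRNA table is empty")
    guides <- vapply(seq_len(nrow(df)), function(k)
        normalize_rna(df$guide[k], what = paste0("guide '", df$id[k], "'")),
        character(1))
    len <- nchar(guides)
    if (any(len < 19L | len > 21L))
        stop("guide length outside 19-21 nt for siRNA '",
             df$id[which(len < 19L | len > 21L)[1]], "'")
    eff <- trimws(as.character(df$efficacy))
    pct <- suppressWarnings(as.numeric(eff))
    cls <- character(nrow(df))
    for (k in seq_len(nrow(df))) {
        if (!is.na(pct[k])) {
            cls[k] <- efficacy_class_from_percent(pct[k])
        } else if (toupper(eff[k]) %in% c("VH", "H", "M", "L")) {
            cls[k] <- toupper(eff[k])
        } else {
            stop("unknown efficacy token '", eff[k], "' for siRNA '",
                 df$id[k], "'")
        }
    }
    data.frame(id = as.character(df$id), guide = guides,
               target_id = as.character(df$target_id),
               efficacy_percent = pct, efficacy_class = cls,
               stringsAsFactors = FALSE, row.names = NULL)
}

# Fixed, documented column order of the feature table.
FEATURE_COLUMNS <- c("sirna_id", "mrna_id", "site_start", "site_end",
                     "efficacy_code", ELEMENT_CLASSES,
                     "n_unpaired", "max_run", "runs",
                     "hb_index", "dg_duplex", "dg_break_target",
                     "dg_oligo_self", "dg_overall", "gc_percent")

#' Write a feature table as TSV
#'
#' Columns in the fixed documented order; reals formatted to 4 decimals so
#' output is deterministic; \code{runs} serialized as a comma-joined list.
#' Round-trips through \code{\link{read_feature_table}} within formatting
#' precision.
#'
#' @param rows feature data.frame (as built by
#'   \code{\link{build_feature_vector}} / \code{\link{compute_features}}).
#' @param path output TSV.
#' @export
write_feature_table <- function(rows, path) {
    out <- as.data.frame(rows, stringsAsFactors = FALSE)
    if (!nrow(out)) {
        writeLines(paste(FEATURE_COLUMNS, collapse = "\t"), path)
        return(invisible(path))
    }
    if (length(miss <- setdiff(FEATURE_COLUMNS, names(out))))
        stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
    out <- out[, FEATURE_COLUMNS]
    for (cn in c("hb_index", "dg_duplex", "dg_break_target",
                 "dg_oligo_self", "dg_overall", "gc_percent"))
        out[[cn]] <- sprintf("%.4f", out[[cn]])
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a feature table written by \code{\link{write_feature_table}}
#' @param path TSV file.
#' @return data.frame in the fixed column order.
#' @export
read_feature_table <- function(path) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = c(runs = "character"))
    if (length(miss <- setdiff(FEATURE_COLUMNS, names(df))))
        stop("not a feature table, lacks: ", paste(miss, collapse = ", "))
    df$runs <- as.character(df$runs)
    df
}
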