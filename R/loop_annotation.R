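# Loop decomposition: classify every nucleotide of a nested secondary
# structure into one of 8 element classes.  Paired positions are STEM; each
# unpaired position belongs to the unique loop closed by its nearest
# enclosing base pair (standard loop decomposition), or to the exterior
# loop.  Loops are classified by their number of interior branches and
# side sizes:
#   0 branches                      -> h_loop   (hairpin)
#   1 branch, both sides > 0        -> int_loop (internal loop)
#   1 branch, sides {1, 0}          -> one_bb   (one-base bulge)
#   1 branch, sides {>=2, 0}        -> b_loop   (bulge)
#   >=2 branches                    -> mb_loop  (multibranch)
# Exterior unpaired positions upstream of the first paired base are loop5,
# downstream of the last paired base loop3; an exterior segment between two
# helices is split at its midpoint (5' half dangles 3' of the preceding
# helix -> loop3; 3' half -> loop5; an odd middle position -> loop5).  A
# structure with no pairs is all loop5.

#' Annotate every position of a structure with its element class
#'
#' @param structure a \code{secondary_structure}.
#' @return object of class \code{element_annotation}: \code{labels}
#'   (character vector over the 8 classes, one per position) and
#'   \code{structure}.
#' @export
annotate <- function(structure) {
    if (!inherits(structure, "secondary_structure"))
        structure <- secondary_structure(structure$sequence, structure$pairs,
                                         structure$energy)
    p <- structure$pairs
    n <- length(p)
    labels <- character(n)
    labels[p > 0L] <- "stem"

    # innermost enclosing opening position for every position (0 = exterior)
    encl <- integer(n)
    stack <- integer(0)
    for (i in seq_len(n)) {
        if (p[i] > i) {                      # opening
            encl[i] <- if (length(stack)) stack[length(stack)] else 0L
            stack <- c(stack, i)
        } else if (p[i] > 0L) {              # closing
            stack <- stack[-length(stack)]
            encl[i] <- if (length(stack)) stack[length(stack)] else 0L
        } else {
            encl[i] <- if (length(stack)) stack[length(stack)] else 0L
        }
    }

    unp <- which(p == 0L)
    # interior loops: group unpaired positions by their enclosing pair
    for (k in unique(encl[unp])) {
        if (k == 0L) next
        l <- p[k]
        members <- unp[encl[unp] == k]
        children <- which(p > seq_len(n) & encl == k)   # openings directly inside
        nb <- length(children)
        lab <- if (nb == 0L) {
            "h_loop"
        } else if (nb == 1L) {
            k2 <- children[1]
            side5 <- k2 - k - 1L
            side3 <- l - p[k2] - 1L
            if (side5 > 0L && side3 > 0L) "int_loop"
            else if (max(side5, side3) == 1L) "one_bb"
            else "b_loop"
        } else "mb_loop"
        labels[members] <- lab
    }

    # exterior loop
    ext <- unp[encl[unp] == 0L]
    if (length(ext)) {
        paired <- which(p > 0L)
        if (!length(paired)) {
            labels[ext] <- "loop5"
        } else {
            first_p <- min(paired); last_p <- max(paired)
            labels[ext[ext < first_p]] <- "loop5"
            labels[ext[ext > last_p]] <- "loop3"
            mid <- ext[ext > first_p & ext < last_p]
            if (length(mid)) {
                # contiguous segments between exterior helices
                seg_id <- cumsum(c(1L, diff(mid) != 1L))
                for (g in unique(seg_id)) {
                    seg <- mid[seg_id == g]
                    m <- length(seg)
                    n3 <- m %/% 2L          # 5' half -> loop3
                    if (n3 > 0L) labels[seg[seq_len(n3)]] <- "loop3"
                    labels[seg[(n3 + 1L):m]] <- "loop5"
                }
            }
        }
    }
    stopifnot(all(nzchar(labels)))
    structure(list(labels = labels, structure = structure),
              class = "element_annotation")
}

#' @export
print.element_annotation <- function(x, ...) {
    cat("element_annotation over", length(x$labels), "positions\n")
    cat(x$structure$sequence, "\n", annotation_string(x), "\n", sep = "")
    invisible(x)
}

# one-letter-per-position debug string: S=stem, H, I, B, O(one-bb), M, 5, 3
#' Compact per-position label string
#' @param annotation an \code{element_annotation}.
#' @return character scalar, one letter per position.
#' @export
annotation_string <- function(annotation) {
    code <- c(stem = "S", h_loop = "H", int_loop = "I", b_loop = "B",
              one_bb = "O", mb_loop = "M", loop5 = "5", loop3 = "3")
    paste(code[annotation$labels], collapse = "")
}

#' Write an annotation as a two-column TSV (position, label)
#' @param annotation an \code{element_annotation}.
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
    write.table(data.frame(position = seq_along(annotation$labels),
                           label = annotation$labels),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Per-element instance counts within a site
#'
#' The alternative counting unit to \code{\link{element_counts_in_site}}:
#' instead of targeted bases per class, the number of distinct structural
#' element instances the window touches.  A stem instance is a helix
#' (maximal stack of consecutive pairs); a loop instance is the loop
#' closed by one enclosing pair; each exterior segment is one instance.
#'
#' @param annotation an \code{element_annotation}.
#' @param site integer vector \code{c(start, end)}.
#' @return named integer vector over the 8 element classes.
#' @export
element_instances_in_site <- function(annotation, site) {
    n <- length(annotation$labels)
    start <- as.integer(site[1]); end <- as.integer(site[2])
    if (is.na(start) || is.na(end) || start < 1L || end > n || start > end)
        stop("site ", start, "..", end, " out of range 1..", n)
    p <- annotation$structure$pairs
    # instance id per position
    ids <- character(n)
    helix <- integer(n)   # helix id for paired positions
    h <- 0L
    for (i in seq_len(n)) {
        if (p[i] > i) {
            # new helix unless stacked on the previous pair
            if (i > 1L && p[i - 1L] == p[i] + 1L) helix[i] <- helix[i - 1L]
            else { h <- h + 1L; helix[i] <- h }
            helix[p[i]] <- helix[i]
        }
    }
    # enclosing opening pair per position (0 = exterior), as in annotate()
    encl <- integer(n); stack <- integer(0)
    for (i in seq_len(n)) {
        if (p[i] > i) {
            encl[i] <- if (length(stack)) stack[length(stack)] else 0L
            stack <- c(stack, i)
        } else if (p[i] > 0L) {
            stack <- stack[-length(stack)]
            encl[i] <- if (length(stack)) stack[length(stack)] else 0L
        } else {
            encl[i] <- if (length(stack)) stack[length(stack)] else 0L
        }
    }
    # exterior segments numbered left to right
    ext_seg <- cumsum(p > 0 | c(TRUE, p[-n] > 0))
    for (i in seq_len(n)) {
        ids[i] <- if (p[i] > 0L) paste0("stem.", helix[i])
                  else if (encl[i] > 0L)
                      paste0(annotation$labels[i], ".", encl[i])
                  else paste0(annotation$labels[i], ".e", ext_seg[i])
    }
    win <- start:end
    counts <- integer(length(ELEMENT_CLASSES))
    names(counts) <- ELEMENT_CLASSES
    for (cl in ELEMENT_CLASSES) {
        sel <- win[annotation$labels[win] == cl]
        counts[[cl]] <- length(unique(ids[sel]))
    }
    counts
}

#' Per-element base counts within a site
#'
#' Counts how many positions of the (1-based, inclusive) window carry each
#' element label; the counts always sum to the window length.
#'
#' @param annotation an \code{element_annotation}.
#' @param site integer vector \code{c(start, end)}.
#' @return named integer vector over the 8 element classes.
#' @export
element_counts_in_site <- function(annotation, site) {
    n <- length(annotation$labels)
    start <- as.integer(site[1]); end <- as.integer(site[2])
    if (is.na(start) || is.na(end) || start < 1L || end > n || start > end)
        stop("site ", start, "..", end, " out of range 1..", n)
    tab <- table(factor(annotation$labels[start:end], levels = ELEMENT_CLASSES))
    counts <- as.integer(tab)
    names(counts) <- ELEMENT_CLASSES
    counts
}
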