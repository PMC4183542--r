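#' @importFrom ape read.tree read.nexus drop.tip getMRCA is.rooted multi2di
#'   node.depth.edgelength postorder
NULL

#' Construct a chronogram from an ape phylo object
#'
#' A chronogram is a rooted, binary, ultrametric tree whose node ages are
#' expressed in time before present (Ma). Node ages are derived root-down from
#' the branch lengths; terminal ages are snapped to exactly 0 when they agree
#' with the root age to within `ul_tol` (relative), and are an error otherwise.
#' Polytomies are resolved arbitrarily into zero-length branches with a
#' warning; the resulting zero-length internal branches are permitted but
#' flagged in the returned object.
#'
#' @param phy an object of class `phylo` with branch lengths.
#' @param ul_tol relative ultrametricity tolerance, as a fraction of root age.
#' @return an object of class `chronogram`: a list with elements `phy`
#'   (the `phylo`, possibly dichotomized), `ages` (node ages in Ma indexed by
#'   ape node number, tips first), `root_age`, `n_tip`, `canon` (deterministic
#'   canonical node ids, see [canonical_ids()]) and `zero_branches` (indices of
#'   flagged zero-length internal edges).
#' @export
as_chronogram <- function(phy, ul_tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths; a dated tree is required")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  phy$tip.label <- .trim_label(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate terminal labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  if (any(phy$tip.label == "")) stop("empty terminal labels are not allowed")
  if (!ape::is.binary(phy)) {
    warning("tree contains polytomies; resolving arbitrarily into zero-length branches")
    phy <- ape::multi2di(phy)
  }
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(n)])
  ages <- root_age - depth
  tip_ages <- ages[seq_len(n)]
  tol <- ul_tol * root_age
  if (any(abs(tip_ages) > tol)) {
    worst <- which.max(abs(tip_ages))
    stop(sprintf(paste0("tree is not ultrametric within tolerance: tip '%s' has age %.6g Ma ",
                        "(root age %.6g Ma, tolerance %.3g)"),
                 phy$tip.label[worst], tip_ages[worst], root_age, tol))
  }
  ages[seq_len(n)] <- 0
  # strictly positive branch durations, except flagged zero-length internal
  # branches left by polytomy resolution
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(dur < -tol)) {
    bad <- which.min(dur)
    stop(sprintf("branch into node %d has negative duration %.6g Ma", phy$edge[bad, 2], dur[bad]))
  }
  zero <- which(dur <= tol & phy$edge[, 2] > n)
  x <- structure(list(phy = phy, ages = ages, root_age = root_age, n_tip = n,
                      zero_branches = zero),
                 class = "chronogram")
  x$canon <- canonical_ids(x)
  x
}

.trim_label <- function(x) gsub("^['\" ]+|['\" ]+$", "", x)

#' Read a dated tree from a Newick or NEXUS file
#'
#' Square-bracket comments (e.g. `[&...]` annotations) are stripped before
#' parsing. If the file contains several trees, the first is returned; use
#' [read_chronogram_ensemble()] for dated-tree ensembles.
#'
#' @param path path to the tree file.
#' @param format `"auto"` (detect NEXUS by the leading `#NEXUS`), `"newick"`
#'   or `"nexus"`.
#' @param ul_tol relative ultrametricity tolerance (see [as_chronogram()]).
#' @return a `chronogram`.
#' @export
read_chronogram <- function(path, format = c("auto", "newick", "nexus"), ul_tol = 1e-6) {
  trees <- .read_trees(path, match.arg(format))
  as_chronogram(trees[[1]], ul_tol = ul_tol)
}

#' Read an ensemble of dated trees (fixed topology, varying ages)
#'
#' @inheritParams read_chronogram
#' @return a list of `chronogram` objects.
#' @export
read_chronogram_ensemble <- function(path, format = c("auto", "newick", "nexus"), ul_tol = 1e-6) {
  trees <- .read_trees(path, match.arg(format))
  lapply(trees, as_chronogram, ul_tol = ul_tol)
}

.read_trees <- function(path, format) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^\\s*#NEXUS", txt, ignore.case = TRUE))) "nexus" else "newick"
  }
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip comments/annotations
  if (format == "nexus") {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf))
    writeLines(txt, tf)
    trees <- ape::read.nexus(tf)
  } else {
    trees <- ape::read.tree(text = paste(txt, collapse = "\n"))
  }
  if (is.null(trees)) stop("could not parse any tree from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(p) {
    if (is.null(p$edge.length)) stop("tree in ", path, " has no branch lengths")
    p
  })
}

#' Deterministic canonical node ids
#'
#' Assigns every node a canonical integer id that depends only on the labelled
#' topology: ids are given in post-order of a traversal in which the children
#' of every node are visited in order of their alphabetically smallest
#' descendant tip label. Two reads of the same tree (or of topologically
#' identical trees with permuted internal node numbering) yield the same
#' id -> leafset map.
#'
#' @param x a `chronogram`.
#' @return integer vector mapping ape node number -> canonical id.
#' @export
canonical_ids <- function(x) {
  phy <- x$phy
  n <- x$n_tip
  m <- phy$Nnode
  minlab <- character(n + m)
  minlab[seq_len(n)] <- phy$tip.label
  po <- ape::postorder(phy)
  e1 <- phy$edge[, 1]; e2 <- phy$edge[, 2]
  for (e in po) {
    p <- e1[e]; ch <- e2[e]
    minlab[p] <- if (minlab[p] == "") minlab[ch] else min(minlab[p], minlab[ch])
  }
  kids <- split(e2, factor(e1, levels = (n + 1):(n + m)))
  canon <- integer(n + m)
  next_id <- 0L
  root <- n + 1L
  # iterative post-order, integer stack; negative entries mark the second
  # (post-children) visit of an internal node
  stack <- integer(2L * (n + m))
  sp <- 1L
  stack[1L] <- root
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    if (v < 0L || v <= n) {
      next_id <- next_id + 1L
      canon[abs(v)] <- next_id
    } else {
      sp <- sp + 1L; stack[sp] <- -v
      ch <- kids[[v - n]]
      if (length(ch) == 2L) {
        # smallest-labelled child popped (hence visited) first
        if (minlab[ch[1L]] > minlab[ch[2L]]) ch <- ch[c(2L, 1L)]
        stack[sp + 1L] <- ch[2L]; stack[sp + 2L] <- ch[1L]
        sp <- sp + 2L
      } else {
        ch <- ch[order(minlab[ch], decreasing = TRUE)]
        for (c0 in ch) { sp <- sp + 1L; stack[sp] <- c0 }
      }
    }
  }
  canon
}

#' Leafset key of a clade
#'
#' The sorted tip labels of the clade subtended by `node`, collapsed into a
#' single string. Used for matching clades across trees that share a label set.
#'
#' @param x a `chronogram` or `richness_tree`.
#' @param node ape node number (tip or internal).
#' @return character scalar.
#' @export
clade_key <- function(x, node) {
  ch <- if (inherits(x, "richness_tree")) x$chronogram else x
  paste(sort(clade_tips(ch, node)), collapse = "|")
}

#' Tip labels of the clade subtended by a node
#' @inheritParams clade_key
#' @return character vector of tip labels.
#' @export
clade_tips <- function(x, node) {
  ch <- if (inherits(x, "richness_tree")) x$chronogram else x
  phy <- ch$phy
  n <- ch$n_tip
  if (node <= n) return(phy$tip.label[node])
  phy$tip.label[.clade_members(phy, node, tips_only = TRUE)]
}

# all nodes (or tips) in the clade rooted at v, including v
.clade_members <- function(phy, v, tips_only = FALSE) {
  n <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x0 <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, x0)
    k <- kids[[as.character(x0)]]
    if (!is.null(k)) stack <- c(stack, k)
  }
  if (tips_only) sort(out[out <= n]) else sort(out)
}

#' Read a terminal richness table
#'
#' Expects a delimited text file (TSV or CSV, sniffed from the header line)
#' with a header and at least two columns: terminal label and extant species
#' count. Counts must be integers >= 1; duplicate labels are an error.
#'
#' @param path path to the table.
#' @return data.frame with columns `label` and `richness`.
#' @export
read_richness <- function(path) {
  if (!file.exists(path)) stop("richness table not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           quote = "\"'", comment.char = "")
  if (ncol(tab) < 2) stop("richness table needs two columns: label, richness")
  richness_table(tab[[1]], tab[[2]])
}

#' Build and validate a richness table in memory
#' @param label terminal labels.
#' @param richness extant species counts (integers >= 1).
#' @return data.frame with columns `label`, `richness`.
#' @export
richness_table <- function(label, richness) {
  label <- .trim_label(as.character(label))
  if (any(is.na(richness)) || any(richness != round(richness)))
    stop("richness counts must be integers")
  richness <- as.integer(richness)
  if (any(richness < 1)) {
    stop("richness must be >= 1 for every terminal; offending: ",
         paste(label[richness < 1], collapse = ", "))
  }
  if (anyDuplicated(label)) {
    stop("duplicate labels in richness table: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  }
  data.frame(label = label, richness = richness, stringsAsFactors = FALSE)
}

#' Join a chronogram with a richness table
#'
#' The label sets must match exactly (case-sensitive, after trimming
#' whitespace and quotes). Per-terminal stem ages (age of the terminal's
#' parent node, the start of its subtending branch) are computed here.
#'
#' @param chronogram a `chronogram`.
#' @param richness data.frame as returned by [read_richness()].
#' @return object of class `richness_tree`: list with `chronogram`, `richness`
#'   (integer vector in tip order), `stem_age` (Ma, in tip order),
#'   `total_richness`, and `edges`, a precomputed branch table used by the
#'   likelihood machinery (columns `parent`, `child`, `t1`, `t2`, `is_term`,
#'   `n`).
#' @export
richness_tree <- function(chronogram, richness) {
  stopifnot(inherits(chronogram, "chronogram"))
  labs <- chronogram$phy$tip.label
  missing_tree <- setdiff(richness$label, labs)
  missing_tab <- setdiff(labs, richness$label)
  if (length(missing_tree) || length(missing_tab)) {
    stop("label mismatch between tree and richness table; ",
         "in table only: {", paste(missing_tree, collapse = ", "), "}; ",
         "in tree only: {", paste(missing_tab, collapse = ", "), "}")
  }
  n <- chronogram$n_tip
  rich <- richness$richness[match(labs, richness$label)]
  phy <- chronogram$phy
  parent_of <- integer(n + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  stem_age <- chronogram$ages[parent_of[seq_len(n)]]
  if (any(stem_age <= 0)) stop("terminal with non-positive stem age")
  edges <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                      t1 = chronogram$ages[phy$edge[, 1]],
                      t2 = chronogram$ages[phy$edge[, 2]],
                      is_term = phy$edge[, 2] <= n,
                      n = ifelse(phy$edge[, 2] <= n, rich[pmin(phy$edge[, 2], n)], NA_integer_))
  # per-node edge sets (stem edge + all clade edges), for regime assignment
  m <- phy$Nnode
  stem_edge <- integer(n + m)
  stem_edge[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  desc <- vector("list", n + m)
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    desc[[p]] <- c(desc[[p]], e, desc[[ch]])   # edge into ch + everything below
  }
  for (v in seq_len(n + m)) {
    if (stem_edge[v] > 0L) desc[[v]] <- c(stem_edge[v], desc[[v]])
  }
  x <- structure(list(chronogram = chronogram, richness = stats::setNames(rich, labs),
                      stem_age = stats::setNames(stem_age, labs),
                      total_richness = sum(rich), edges = edges,
                      edge_desc = desc, stem_edge = stem_edge),
                 class = "richness_tree")
  message(sprintf("joined %d terminals; total richness %d species", n, x$total_richness))
  x
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("chronogram: %d terminals, root age %.4g Ma\n", x$n_tip, x$root_age))
  if (length(x$zero_branches))
    cat(sprintf("  (%d zero-length internal branches flagged)\n", length(x$zero_branches)))
  invisible(x)
}

#' @export
print.richness_tree <- function(x, ...) {
  cat(sprintf("richness tree: %d terminals, total richness %d, root age %.4g Ma\n",
              x$chronogram$n_tip, x$total_richness, x$chronogram$root_age))
  invisible(x)
}

#' Write a dated tree to NEXUS with optional per-node annotations
#'
#' Annotations are written as square-bracket comments (`[&key=value,...]`)
#' attached to the annotated node, the style used for figure-ready shift and
#' robustness markup. Ages survive a round trip through [read_chronogram()]
#' (which strips the comments) to within 1e-9 Ma.
#'
#' @param x a `chronogram` or `richness_tree`.
#' @param path output path.
#' @param annotations `NULL`, or a named list: names are ape node numbers,
#'   each element a named character/numeric vector of key-value pairs.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(x, path, annotations = NULL) {
  ch <- if (inherits(x, "richness_tree")) x$chronogram else x
  stopifnot(inherits(ch, "chronogram"))
  phy <- ch$phy
  n <- ch$n_tip
  if (!is.null(annotations)) {
    ids <- as.integer(names(annotations))
    if (any(is.na(ids)) || any(ids < 1) || any(ids > n + phy$Nnode))
      stop("annotation references unknown node id: ",
           paste(names(annotations)[is.na(ids) | ids < 1 | ids > n + phy$Nnode], collapse = ", "))
  }
  cmt <- function(v) {
    a <- annotations[[as.character(v)]]
    if (is.null(a)) return("")
    paste0("[&", paste(names(a), unname(a), sep = "=", collapse = ","), "]")
  }
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  len <- numeric(n + phy$Nnode)
  len[phy$edge[, 2]] <- ch$ages[phy$edge[, 1]] - ch$ages[phy$edge[, 2]]
  build <- function(v) {
    if (v <= n) return(sprintf("%s%s:%.15g", phy$tip.label[v], cmt(v), len[v]))
    inner <- paste(vapply(kids[[as.character(v)]], build, ""), collapse = ",")
    if (v == n + 1L) sprintf("(%s)%s", inner, cmt(v)) else sprintf("(%s)%s:%.15g", inner, cmt(v), len[v])
  }
  nwk <- paste0(build(n + 1L), ";")
  writeLines(c("#NEXUS", "begin trees;", paste0("\ttree TREE1 = [&R] ", nwk), "end;"), path)
  invisible(path)
}

#' Write one or more chronograms as a plain Newick file
#' @param x a `chronogram` or list of chronograms.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chronogram <- function(x, path) {
  if (inherits(x, "chronogram")) x <- list(x)
  lines <- vapply(x, function(ch) ape::write.tree(ch$phy), "")
  writeLines(lines, path)
  invisible(path)
}

#' Resolve a clade from a set of tip labels
#'
#' Returns the MRCA node of the given labels. If `exact = TRUE`, the MRCA's
#' leafset must equal the given label set.
#'
#' @param x a `chronogram` or `richness_tree`.
#' @param tips character vector of tip labels.
#' @param exact require the labels to form exactly the MRCA's clade.
#' @return ape node number.
#' @export
resolve_clade <- function(x, tips, exact = FALSE) {
  ch <- if (inherits(x, "richness_tree")) x$chronogram else x
  idx <- match(tips, ch$phy$tip.label)
  if (anyNA(idx)) stop("unknown tip labels: ", paste(tips[is.na(idx)], collapse = ", "))
  node <- if (length(idx) == 1L) idx else ape::getMRCA(ch$phy, idx)
  if (exact && !setequal(clade_tips(ch, node), tips))
    stop("labels do not form a clade (MRCA leafset is larger)")
  node
}
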