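#' @useDynLib coraldepth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import ape
#' @importFrom Matrix expm
#' @importFrom stats median rnorm runif rexp sd quantile setNames complete.cases
#' @importFrom utils head tail
NULL

# Internal marker used to smuggle branch-scalar annotations through the
# plain-Newick label field; converted to/from "[&r=...]" comment tags.
.rtag <- "__RTAG_"

#' Time trees with branch rate scalars
#'
#' A `timetree` is an [ape::read.tree()]-style `phylo` object (rooted, branch
#' lengths in Ma) augmented with a numeric `scalar` vector holding one
#' dimensionless rate scalar r per branch (row of `$edge`).  `r = 1` means the
#' branch evolves at the background rate; `r > 1` is stretched (accelerated
#' trait change), `0 < r < 1` compressed (decelerated).  Node indices follow
#' the `ape` convention: tips `1..n`, root `n+1`, stable across operations.
#'
#' @param phy a `phylo` object (rooted, with branch lengths).
#' @param scalar numeric vector of branch scalars, one per edge; default all 1.
#' @return an object of class `c("timetree", "phylo")`.
#' @export
timetree <- function(phy, scalar = NULL) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  ne <- nrow(phy$edge)
  if (is.null(scalar)) scalar <- rep(1, ne)
  if (length(scalar) != ne) stop("'scalar' must have one value per branch")
  if (any(!is.finite(scalar)) || any(scalar <= 0)) stop("branch scalars must be positive")
  phy$scalar <- as.numeric(scalar)
  class(phy) <- unique(c("timetree", class(phy)))
  phy
}

#' @rdname timetree
#' @param x object to coerce or test.
#' @export
as_timetree <- function(x) {
  if (inherits(x, "timetree")) return(x)
  timetree(x)
}

#' Branch scalars of a timetree
#'
#' @param tree a `timetree`.
#' @return numeric vector of per-branch scalars (length `Nedge(tree)`).
#' @export
branch_scalars <- function(tree) {
  if (is.null(tree$scalar)) rep(1, nrow(tree$edge)) else tree$scalar
}

#' @rdname branch_scalars
#' @param value replacement scalar vector.
#' @export
`branch_scalars<-` <- function(tree, value) {
  timetree(tree, scalar = value)
}

#' Read a time-calibrated tree (Newick or NEXUS), with scalar annotations
#'
#' Accepts plain Newick/NEXUS or the annotated Newick written by
#' [write_timetree()], in which a branch's rate scalar is carried as a
#' BEAST-style comment tag `[&r=...]` placed before the branch length.
#' Tags are optional; untagged branches get `r = 1`.
#'
#' @param source a file path, or a character string containing the tree text.
#' @return a [timetree()].
#' @export
read_timetree <- function(source) {
  txt <- if (length(source) == 1 && !grepl("(", source, fixed = TRUE) &&
             file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex"); on.exit(unlink(tf))
    writeLines(txt, tf)
    phy <- ape::read.nexus(tf)
    if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
    return(timetree(phy))
  }
  .check_newick(txt)
  # stash "[&r=x]" comment tags into the adjacent label so ape keeps them
  txt2 <- gsub("\\[&r=([0-9eE.+-]+)\\]", paste0(.rtag, "\\1__"), txt)
  if (grepl("\\[", txt2)) txt2 <- gsub("\\[[^]]*\\]", "", txt2)  # drop other comments
  phy <- tryCatch(ape::read.tree(text = txt2),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: unreadable tree text")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ne <- nrow(phy$edge)
  scalar <- rep(1, ne)
  grab <- function(labels, ids) {
    hit <- regmatches(labels, regexpr(paste0(.rtag, "[0-9eE.+-]+__"), labels))
    has <- grepl(.rtag, labels, fixed = TRUE)
    if (any(has)) {
      vals <- as.numeric(sub("__$", "", sub(.rtag, "", hit, fixed = TRUE)))
      for (i in which(has)) {
        e <- which(phy$edge[, 2] == ids[i])
        if (length(e) == 1) scalar[e] <<- vals[match(i, which(has))]
      }
      labels[has] <- sub(paste0(.rtag, "[0-9eE.+-]+__"), "", labels[has])
    }
    labels
  }
  phy$tip.label <- grab(phy$tip.label, seq_len(ape::Ntip(phy)))
  if (!is.null(phy$node.label)) {
    phy$node.label <- grab(phy$node.label, ape::Ntip(phy) + seq_len(phy$Nnode))
    if (all(phy$node.label == "")) phy$node.label <- NULL
  }
  timetree(phy, scalar)
}

# minimal structural validation with a position in the error message
.check_newick <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") {
      depth <- depth - 1
      if (depth < 0) stop("Newick parse error at position ", i, ": unmatched ')'")
    }
  }
  if (depth != 0) stop("Newick parse error at position ", nchar(txt),
                       ": ", depth, " unclosed '('")
  if (!grepl(";", txt)) stop("Newick parse error at position ", nchar(txt),
                             ": missing terminal ';'")
  invisible(TRUE)
}

#' Write a timetree as (annotated) Newick or NEXUS
#'
#' Branches with scalar r != 1 get a `[&r=...]` comment tag before the branch
#' length; trees with all scalars 1 serialize as plain Newick.
#'
#' @param tree a [timetree()].
#' @param path optional output file; if `NULL` the text is returned.
#' @param format `"newick"` or `"nexus"` (NEXUS drops scalar tags).
#' @param digits significant digits for branch lengths.
#' @return the serialized text, invisibly when `path` is given.
#' @export
write_timetree <- function(tree, path = NULL, format = c("newick", "nexus"),
                           digits = 10) {
  format <- match.arg(format)
  tree <- as_timetree(tree)
  if (format == "nexus") {
    tf <- tempfile(); on.exit(unlink(tf))
    ape::write.nexus(tree, file = tf)
    txt <- paste(readLines(tf, warn = FALSE), collapse = "\n")
  } else {
    phy <- tree
    sc <- branch_scalars(tree)
    tagged <- which(abs(sc - 1) > 0)
    if (length(tagged)) {
      ntip <- ape::Ntip(phy)
      if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
      for (e in tagged) {
        child <- phy$edge[e, 2]
        tag <- paste0(.rtag, format(sc[e], digits = digits, scientific = FALSE), "__")
        if (child <= ntip) phy$tip.label[child] <- paste0(phy$tip.label[child], tag)
        else phy$node.label[child - ntip] <- paste0(phy$node.label[child - ntip], tag)
      }
    }
    txt <- ape::write.tree(phy, digits = digits)
    txt <- gsub(paste0(.rtag, "([0-9eE.+-]+)__"), "[&r=\\1]", txt)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Node ages in Ma before present
#'
#' Ages are root age minus root-to-node path length, with root age taken as
#' the maximum root-to-tip distance (exact for ultrametric, time-calibrated
#' trees; for non-ultrametric trees ages are relative to the most recent tip).
#'
#' @param tree a [timetree()].
#' @return numeric vector over all nodes (ape indices `1..(2n-1)`).
#' @export
node_ages <- function(tree) {
  tree <- as_timetree(tree)
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

#' Node table (id, age, tip flag)
#'
#' @param tree a [timetree()].
#' @return data.frame with `node_id`, `age_ma`, `is_tip`, `label`.
#' @export
node_table <- function(tree) {
  tree <- as_timetree(tree)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  lab <- c(tree$tip.label,
           if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode)
           else tree$node.label)
  data.frame(node_id = seq_len(ntot), age_ma = node_ages(tree),
             is_tip = seq_len(ntot) <= ntip, label = lab,
             stringsAsFactors = FALSE)
}

#' Enumerate phylogenetic ancestor-descendant (PAD) pairs
#'
#' One pair per branch: the nodes at the two ends of each edge.  Any root
#' edge (`$root.edge`) is ignored, so a binary tree with n tips yields
#' exactly 2n-2 pairs.  A single-tip tree `(A:1);` has one stored edge and
#' yields one pair.
#'
#' @param tree a rooted [timetree()].
#' @return data.frame with `branch_id`, `ancestor`, `descendant`.
#' @export
enumerate_pads <- function(tree) {
  tree <- as_timetree(tree)
  if (!ape::is.rooted(tree)) stop("PAD enumeration requires a rooted tree")
  data.frame(branch_id = seq_len(nrow(tree$edge)),
             ancestor = tree$edge[, 1], descendant = tree$edge[, 2])
}

#' Path-wise distance from the root
#'
#' Sum of branch lengths (optionally multiplied by their rate scalars) along
#' the root-to-node path.  On a rate-scaled tree this is the "path-wise rate":
#' lineages with much cumulative trait change accumulate large values.
#'
#' @param tree a [timetree()].
#' @param node node id(s); default all nodes.
#' @param use_scalars multiply each branch length by its scalar r?
#' @return numeric vector of distances (Ma, scaled if `use_scalars`).
#' @export
path_wise_distance <- function(tree, node = NULL, use_scalars = TRUE) {
  tree <- as_timetree(tree)
  phy <- tree
  if (use_scalars) phy$edge.length <- phy$edge.length * branch_scalars(tree)
  d <- ape::node.depth.edgelength(phy)
  if (is.null(node)) return(d)
  ntot <- ape::Ntip(tree) + tree$Nnode
  if (any(node < 1 | node > ntot)) stop("unknown node id")
  d[node]
}

#' Attach zero-length false tips at every internal node
#'
#' Grafts one zero-length pseudo-tip ("false tip") onto each internal node,
#' root included, so that a predictive regression model can produce fitted
#' values at ancestral nodes.  An n-tip binary tree gains n-1 tips, for
#' 2n-1 tips in total.  Original path-wise distances are unchanged and each
#' false tip inherits its host's root-to-node distance exactly.
#'
#' @param tree a [timetree()].
#' @param prefix label prefix for the new tips; labels are `<prefix><host id>`
#'   with host ids referring to the *original* tree's node numbering.
#' @return a [timetree()] with attribute `"host_map"`: data.frame
#'   `false_tip` (new tip id), `host` (new id of host node), `host_orig`
#'   (host id in the original tree).
#' @export
attach_false_tips <- function(tree, prefix = "FT") {
  tree <- as_timetree(tree)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  m <- nnode                       # one false tip per internal node
  old_edge <- tree$edge
  # new ids: original tips keep 1..ntip; false tips ntip+1..ntip+m;
  # original internal node k (ntip+1..ntip+nnode) -> k + m
  remap <- function(id) ifelse(id <= ntip, id, id + m)
  new_edge <- cbind(remap(old_edge[, 1]), remap(old_edge[, 2]))
  hosts_orig <- ntip + seq_len(nnode)
  ft_ids <- ntip + seq_len(m)
  add_edge <- cbind(hosts_orig + m, ft_ids)
  phy <- list(edge = rbind(new_edge, add_edge),
              edge.length = c(tree$edge.length, rep(0, m)),
              tip.label = c(tree$tip.label, paste0(prefix, hosts_orig)),
              Nnode = nnode)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  # scalars travel with edges through the reorder
  sc_all <- c(branch_scalars(tree), rep(1, m))
  out <- timetree(phy, scalar = sc_all[match(.edge_key(phy$edge),
                                             .edge_key(rbind(new_edge, add_edge)))])
  attr(out, "host_map") <- data.frame(false_tip = ft_ids,
                                      host = hosts_orig + m,
                                      host_orig = hosts_orig)
  out
}

.edge_key <- function(edge) paste(edge[, 1], edge[, 2], sep = "-")

# postorder edge ordering + components used by the C likelihood routines
.postorder_parts <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  list(edge = tree$edge[po, , drop = FALSE], order = po)
}
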