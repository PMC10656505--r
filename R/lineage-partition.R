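# Trait calls at nodes and the 16 -> 8 branch category merge.

#' Per-trait node calls from 4-state posteriors
#'
#' For each node the posterior over the four combined states is collapsed
#' into per-trait marginals (symbiosis: azooxanthellate vs zooxanthellate;
#' coloniality: solitary vs colonial).  A trait state is called when its
#' marginal reaches `threshold`; otherwise the trait is uncertain — no state
#' can be assigned with enough statistical support.
#'
#' @param probs nodes x 4 matrix (columns AS, AC, ZS, ZC), e.g. from
#'   [node_state_posteriors()].
#' @param threshold support threshold in `(0.5, 1]`.
#' @return data.frame with `node_id`, `symbiosis`
#'   (`"azoox"`/`"zoox"`/`"uncertain"`), `coloniality`
#'   (`"solitary"`/`"colonial"`/`"uncertain"`).
#' @export
assign_node_states <- function(probs, threshold = 0.7) {
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 state columns (AS, AC, ZS, ZC)")
  if (is.null(colnames(probs))) colnames(probs) <- lineage_states()
  p_az <- probs[, "AS"] + probs[, "AC"]
  p_sol <- probs[, "AS"] + probs[, "ZS"]
  call2 <- function(p, yes, no)
    ifelse(p >= threshold, yes, ifelse(1 - p >= threshold, no, "uncertain"))
  data.frame(node_id = seq_len(nrow(probs)),
             symbiosis = call2(p_az, "azoox", "zoox"),
             coloniality = call2(p_sol, "solitary", "colonial"),
             stringsAsFactors = FALSE)
}

# per-trait branch status from the calls at the two ends of the branch
.branch_trait_status <- function(anc, dec) {
  ifelse(anc == "uncertain" | dec == "uncertain", "uncertain",
         ifelse(anc == dec, dec, "transition"))
}

#' Classify branches into the eight trait-defined lineage categories
#'
#' Each branch gets, per trait, one of four statuses from the calls at its
#' two ends: a state (same call at both ends), a transition (different
#' assigned states — the origin of a trait state on that branch) or
#' uncertain (either end uncertain).  The 16 raw status combinations are
#' merged to eight categories: the four stable classes AS/AC/ZS/ZC;
#' TransS (symbiosis transition, any coloniality status); TransC
#' (coloniality transition with symbiosis assigned); UncS (symbiosis
#' uncertain, coloniality colonial or uncertain); UncC (coloniality
#' uncertain, symbiosis assigned).  Three raw combinations
#' (transition-transition, uncertain-solitary, uncertain-transition) fall in
#' no category and are excluded with a log entry.
#'
#' @param tree a [timetree()].
#' @param node_calls data.frame from [assign_node_states()] covering every
#'   node of the tree.
#' @return data.frame with `branch_id`, `ancestor`, `descendant`,
#'   `symbiosis_status`, `coloniality_status`, `raw_label`, `category`
#'   (`NA` for excluded branches); attribute `"excluded"` lists excluded
#'   branches and the offending raw label.
#' @export
classify_branches <- function(tree, node_calls) {
  tree <- as_timetree(tree)
  ntot <- ape::Ntip(tree) + tree$Nnode
  if (!all(seq_len(ntot) %in% node_calls$node_id))
    stop("node_calls must cover every node")
  symb <- stats::setNames(node_calls$symbiosis, node_calls$node_id)
  col <- stats::setNames(node_calls$coloniality, node_calls$node_id)
  anc <- as.character(tree$edge[, 1]); dec <- as.character(tree$edge[, 2])
  s_st <- .branch_trait_status(symb[anc], symb[dec])
  c_st <- .branch_trait_status(col[anc], col[dec])
  raw <- paste(s_st, c_st, sep = "-")
  category <- character(length(raw))
  for (i in seq_along(raw)) {
    category[i] <- if (s_st[i] == "transition" && c_st[i] == "transition") NA_character_
    else if (s_st[i] == "transition") "TransS"
    else if (c_st[i] == "transition") {
      if (s_st[i] == "uncertain") NA_character_ else "TransC"
    }
    else if (s_st[i] == "uncertain") {
      if (c_st[i] == "solitary") NA_character_ else "UncS"
    }
    else if (c_st[i] == "uncertain") "UncC"
    else paste0(ifelse(s_st[i] == "azoox", "A", "Z"),
                ifelse(c_st[i] == "solitary", "S", "C"))
  }
  out <- data.frame(branch_id = seq_along(raw),
                    ancestor = tree$edge[, 1], descendant = tree$edge[, 2],
                    symbiosis_status = unname(s_st),
                    coloniality_status = unname(c_st),
                    raw_label = raw, category = category,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- out[is.na(out$category),
                               c("branch_id", "raw_label")]
  out
}

#' All eight lineage categories
#' @return character vector of the merged branch classes.
#' @export
lineage_categories <- function()
  c("AS", "AC", "ZS", "ZC", "TransS", "TransC", "UncS", "UncC")

#' Merge raw 16-way status counts into the eight categories
#'
#' Utility for tables of raw per-trait status combinations: sums the counts
#' absorbed by each merged category and reports the excluded combinations.
#'
#' @param counts data.frame with `symbiosis_status`, `coloniality_status`,
#'   `n` (symbiosis: `azoox`/`zoox`/`transition`/`uncertain`; coloniality:
#'   `solitary`/`colonial`/`transition`/`uncertain`).
#' @return named vector of counts over `lineage_categories()`, with
#'   attribute `"excluded"` (the dropped combinations and their counts).
#' @export
merge_category_counts <- function(counts) {
  cat_of <- function(s, cc) {
    if (s == "transition" && cc == "transition") return(NA_character_)
    if (s == "transition") return("TransS")
    if (cc == "transition") return(if (s == "uncertain") NA_character_ else "TransC")
    if (s == "uncertain") return(if (cc == "solitary") NA_character_ else "UncS")
    if (cc == "uncertain") return("UncC")
    paste0(ifelse(s == "azoox", "A", "Z"), ifelse(cc == "solitary", "S", "C"))
  }
  cats <- mapply(cat_of, counts$symbiosis_status, counts$coloniality_status)
  out <- stats::setNames(numeric(length(lineage_categories())), lineage_categories())
  for (i in seq_along(cats)) if (!is.na(cats[i])) out[cats[i]] <- out[cats[i]] + counts$n[i]
  attr(out, "excluded") <- counts[is.na(cats), , drop = FALSE]
  out
}
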