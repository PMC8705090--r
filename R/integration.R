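## Integration of DE miRs/isomiRs with DE mRNAs and TF-miR regulations:
## score-filtered target tables -> sign-correlated expression pairs ->
## TF-miR/isomiR-gene regulatory circuit.

.armFamily <- function(armName) sub("-[35]p$", "", armName)

#' Filter a target-prediction table by score
#'
#' Keeps predicted (regulator, gene) rows whose confidence score reaches
#' the threshold (inclusive); scores live on a 0-100 scale.
#'
#' @param targets data.frame with columns `regulator`, `gene`, `score`.
#' @param minScore Minimum score to keep (default 80).
#' @return The filtered data.frame.
#' @export
filterTargets <- function(targets, minScore = 80) {
    stopifnot(all(c("regulator", "gene", "score") %in% colnames(targets)))
    if (any(is.na(targets$score)) || any(targets$score < 0) ||
        any(targets$score > 100))
        stop("target scores must lie in [0, 100]")
    out <- targets[targets$score >= minScore, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Pair DE miRs/isomiRs with DE genes through a target table
#'
#' Forms one expression pair per (regulator, gene) combination present in
#' the (already score-filtered) target table with both sides
#' differentially expressed. The pair class is `negative` when the two
#' log2 fold changes have opposite signs and `positive` otherwise.
#' Variants whose seed is unshifted (5' offset 0: the reference, 3'-only
#' and purely tailed variants) inherit the parent arm's target rows when
#' the table carries no rows under their own canonical name; 5'-shifted
#' variants have a different seed and must carry their own rows.
#'
#' @param mirDE data.frame from [callDE()] on the miR/isomiR matrix
#'   (columns `feature`, `log2FC`).
#' @param geneDE data.frame from [callDE()] on the gene matrix.
#' @param targets Score-filtered target table ([filterTargets()]).
#' @param inheritSeedMatched Inherit parent rows for seed-unshifted
#'   variants without rows of their own (default TRUE).
#' @return data.frame with columns `regulator`, `gene`, `regulatorLFC`,
#'   `geneLFC`, `klass`, ordered lexicographically by (regulator, gene).
#' @export
pairDE <- function(mirDE, geneDE, targets, inheritSeedMatched = TRUE) {
    regLfc <- stats::setNames(mirDE$log2FC, mirDE$feature)
    genLfc <- stats::setNames(geneDE$log2FC, geneDE$feature)
    rows <- list()
    for (feat in names(regLfc)) {
        hit <- targets[targets$regulator == feat, , drop = FALSE]
        if (nrow(hit) == 0L && inheritSeedMatched) {
            pf <- parseName(feat)
            if (pf$offset5 == 0L && pf$parent != feat)
                hit <- targets[targets$regulator == pf$parent, ,
                               drop = FALSE]
        }
        if (nrow(hit) == 0L) next
        genes <- intersect(unique(hit$gene), names(genLfc))
        if (length(genes) == 0L) next
        rows[[feat]] <- data.frame(
            regulator = feat, gene = genes,
            regulatorLFC = unname(regLfc[feat]),
            geneLFC = unname(genLfc[genes]),
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(regulator = character(), gene = character(),
                          regulatorLFC = numeric(), geneLFC = numeric(),
                          klass = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, unname(rows))
    out <- out[!duplicated(out[, c("regulator", "gene")]), , drop = FALSE]
    prod <- out$regulatorLFC * out$geneLFC
    if (any(prod == 0))
        warning("pair with zero fold-change product classified positive")
    out$klass <- ifelse(prod < 0, "negative", "positive")
    out <- out[order(out$regulator, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Genes targeted by multiple distinct regulators
#'
#' Counts, among negative pairs, how many distinct miR/isomiR regulators
#' target each gene (a reference miR and its isomiRs count separately).
#' The multi-targeted subset is `nRegulators >= 2`.
#'
#' @param pairs data.frame with columns `regulator`, `gene`, and
#'   optionally `klass` (only `negative` rows are used when present).
#' @return data.frame (`gene`, `nRegulators`) sorted by decreasing count,
#'   then gene name.
#' @export
multiTargetGenes <- function(pairs) {
    stopifnot(all(c("regulator", "gene") %in% colnames(pairs)))
    if ("klass" %in% colnames(pairs))
        pairs <- pairs[pairs$klass == "negative", , drop = FALSE]
    pairs <- pairs[!duplicated(pairs[, c("regulator", "gene")]), ,
                   drop = FALSE]
    n <- tapply(pairs$regulator, pairs$gene,
                function(r) length(unique(r)))
    out <- data.frame(gene = names(n), nRegulators = as.integer(n),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$nRegulators, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Expand TF-miR regulations to DE isomiR features
#'
#' A TF regulating a miR family regulates every expressed variant of that
#' family, because isomiRs and their reference miR are transcribed from
#' the same gene. A regulation on family `miR-92a` (or directly on an arm
#' such as `miR-92a-3p`) therefore yields one edge per DE feature whose
#' parent arm belongs to that family. Only literature-curated records are
#' used by default.
#'
#' @param regulations data.frame with columns `tf`, `mir_family`,
#'   `direction`, `literature_curated`.
#' @param deFeatures Character vector of DE canonical feature names.
#' @param curatedOnly Drop non-curated records (default TRUE).
#' @return data.frame with columns `tf`, `feature`.
#' @export
expandTFRegulations <- function(regulations, deFeatures,
                                curatedOnly = TRUE) {
    stopifnot(all(c("tf", "mir_family") %in% colnames(regulations)))
    if (curatedOnly && "literature_curated" %in% colnames(regulations))
        regulations <- regulations[
            as.logical(regulations$literature_curated), , drop = FALSE]
    if (length(deFeatures) == 0L || nrow(regulations) == 0L)
        return(data.frame(tf = character(), feature = character(),
                          stringsAsFactors = FALSE))
    parsed <- .parseNames(deFeatures)
    fam <- .armFamily(parsed$parent)
    rows <- list()
    for (i in seq_len(nrow(regulations))) {
        key <- regulations$mir_family[i]
        match_ <- fam == key | parsed$parent == key
        if (!any(match_)) next
        rows[[i]] <- data.frame(tf = regulations$tf[i],
                                feature = deFeatures[match_],
                                stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(tf = character(), feature = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out), , drop = FALSE]
    out <- out[order(out$tf, out$feature), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Assemble the TF-miR/isomiR-gene regulatory circuit
#'
#' Builds a typed directed graph from (i) negative expression pairs,
#' wired as `mir_targets_gene` edges (the regulatory reading: miRs act as
#' negative post-transcriptional regulators; positive pairs are reported
#' upstream but not wired), and (ii) expanded TF regulations, wired as
#' `tf_regulates_mir` edges. isomiR features are collapsed into family
#' nodes labelled by their parent mature arm, with the number of
#' collapsed features recorded as node multiplicity.
#'
#' @param pairs data.frame from [pairDE()].
#' @param tfEdges data.frame from [expandTFRegulations()].
#' @param deTFGenes Character vector of DE gene symbols that are
#'   transcription factors; these nodes are typed `TF`.
#' @return A [RegulatoryCircuit-class].
#' @export
buildCircuit <- function(pairs, tfEdges,
                         deTFGenes = character()) {
    neg <- pairs[pairs$klass == "negative", , drop = FALSE]
    ## family node label = parent mature arm of the feature
    famOf <- function(feats)
        vapply(feats, function(f) parseName(f)$parent, "")

    mirFeat <- unique(c(neg$regulator, tfEdges$feature))
    mirFam <- famOf(mirFeat)
    famTab <- table(mirFam)

    tgEdge <- if (nrow(neg)) unique(data.frame(
        src = unname(famOf(neg$regulator)), dst = neg$gene,
        type = "mir_targets_gene", stringsAsFactors = FALSE))
        else data.frame(src = character(), dst = character(),
                        type = character(), stringsAsFactors = FALSE)
    tfEdge <- if (nrow(tfEdges)) unique(data.frame(
        src = tfEdges$tf, dst = unname(famOf(tfEdges$feature)),
        type = "tf_regulates_mir", stringsAsFactors = FALSE))
        else data.frame(src = character(), dst = character(),
                        type = character(), stringsAsFactors = FALSE)

    tfNodes <- unique(c(tfEdge$src, intersect(deTFGenes, tgEdge$dst)))
    geneNodes <- setdiff(unique(tgEdge$dst), tfNodes)
    famNodes <- sort(unique(names(famTab)))
    nodes <- rbind(
        data.frame(name = sort(tfNodes), type = rep("TF", length(tfNodes)),
                   multiplicity = rep(1L, length(tfNodes)),
                   stringsAsFactors = FALSE),
        data.frame(name = famNodes,
                   type = rep("mir_family", length(famNodes)),
                   multiplicity = as.integer(famTab[famNodes]),
                   stringsAsFactors = FALSE),
        data.frame(name = sort(geneNodes),
                   type = rep("gene", length(geneNodes)),
                   multiplicity = rep(1L, length(geneNodes)),
                   stringsAsFactors = FALSE))
    edges <- rbind(tfEdge, tgEdge)
    edges <- edges[order(edges$type, edges$src, edges$dst), , drop = FALSE]
    rownames(nodes) <- NULL
    rownames(edges) <- NULL
    new("RegulatoryCircuit", nodes = nodes, edges = edges)
}

#' @describeIn RegulatoryCircuit-class Node table of a circuit.
#' @param x A `RegulatoryCircuit`.
#' @export
circuitNodes <- function(x) x@nodes

#' @describeIn RegulatoryCircuit-class Edge table of a circuit.
#' @export
circuitEdges <- function(x) x@edges

setMethod("show", "RegulatoryCircuit", function(object) {
    tab <- table(object@nodes$type)
    cat(sprintf(
        "RegulatoryCircuit: %d nodes (%s), %d edges\n",
        nrow(object@nodes),
        paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
        nrow(object@edges)))
})

#' Export a circuit as DOT and/or an edge-list TSV
#'
#' The DOT output types nodes by shape (TF box, mir_family ellipse, gene
#' plaintext); the TSV has columns `src`, `dst`, `edge_type`. Both exports
#' are lossless with respect to the edge set.
#'
#' @param circuit A [RegulatoryCircuit-class].
#' @param dotPath,edgesPath Output paths (either may be NULL).
#' @export
writeCircuit <- function(circuit, dotPath = NULL, edgesPath = NULL) {
    ed <- circuit@edges
    nd <- circuit@nodes
    if (!is.null(edgesPath)) {
        out <- data.frame(src = ed$src, dst = ed$dst, edge_type = ed$type)
        utils::write.table(out, edgesPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    if (!is.null(dotPath)) {
        shape <- c(TF = "box", mir_family = "ellipse", gene = "plaintext")
        lines <- c("digraph circuit {",
            sprintf("  \"%s\" [shape=%s, type=\"%s\"];",
                    nd$name, shape[nd$type], nd$type),
            sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                    ed$src, ed$dst, ed$type),
            "}")
        writeLines(lines, dotPath)
    }
    invisible(circuit)
}

#' Is there a directed path through the circuit?
#'
#' Convenience check for motifs such as TF -> miR family -> TF gene.
#'
#' @param circuit A [RegulatoryCircuit-class].
#' @param nodes Character vector of node names forming the path, in
#'   order.
#' @return TRUE if every consecutive node pair is an edge.
#' @export
hasPath <- function(circuit, nodes) {
    if (length(nodes) < 2L) return(TRUE)
    ed <- circuit@edges
    all(vapply(seq_len(length(nodes) - 1L), function(i)
        any(ed$src == nodes[i] & ed$dst == nodes[i + 1L]), TRUE))
}

#' Partition two name sets into exclusive and shared members
#'
#' Used, e.g., to compare the DE features found at two time points of a
#' contrast series.
#'
#' @param a,b Character vectors.
#' @return A list with sorted components `only_a`, `only_b`, `shared`,
#'   plus an attribute `counts` (named integer vector).
#' @export
compareSets <- function(a, b) {
    a <- unique(a); b <- unique(b)
    out <- list(only_a = sort(setdiff(a, b)),
                only_b = sort(setdiff(b, a)),
                shared = sort(intersect(a, b)))
    attr(out, "counts") <- vapply(out, length, 0L)
    out
}

#' Curated negative miR/isomiR-target pairs of the receptive endometrium
#'
#' The packaged table of negatively correlating DE miR/isomiR-gene target
#' pairs reported for receptive-phase endometrium (regulators named in
#' the canonical isomiR nomenclature). Useful as a realistic fixture for
#' [multiTargetGenes()] and the pairing machinery.
#'
#' @return data.frame with columns `family`, `regulator`, `gene`.
#' @export
receptivePairsTable <- function() {
    path <- system.file("extdata", "receptive_negative_pairs.tsv",
                        package = "isomiRpipe", mustWork = TRUE)
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}
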