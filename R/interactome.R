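# Cell-cell interaction core: condition-split grouping, secreted-ligand
# extraction, secreting-capacity z-score ranking, the GO cross-match, and
# product-of-means ligand-receptor scoring.

#' Condition-split group labels
#'
#' Every cluster is scored as two populations: \code{n-<cluster>} (non-AD
#' cells) and \code{d-<cluster>} (AD cells). Groups below \code{minCells}
#' are dropped (their cells get NA) with a warning.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{cluster} and
#'   \code{condition} cell metadata.
#' @param minCells minimum cells per condition-split group.
#' @return character vector of per-cell group labels (NA for dropped).
#' @export
conditionGroups <- function(sce, minCells = 10) {
    cluster <- as.character(colData(sce)$cluster)
    condition <- .checkCondition(colData(sce)$condition)
    g <- paste0(ifelse(condition == "AD", "d-", "n-"), cluster)
    sizes <- table(g)
    small <- names(sizes)[sizes < minCells]
    if (length(small)) {
        warning("dropping condition-split group(s) below ", minCells,
                " cells: ", paste(small, collapse = ", "))
        g[g %in% small] <- NA_character_
    }
    g
}

#' Extract candidate ligands per group from cluster markers
#'
#' Intersects each group's positive markers with the database's secreted
#' gene set.
#'
#' @param markers a marker table from [findAllMarkers()] (already
#'   q-filtered, positive markers).
#' @param db a [LigandReceptorDB-class].
#' @return named list, group -> sorted ligand gene set (subset of the
#'   secreted genes).
#' @export
extractClusterLigands <- function(markers, db) {
    stopifnot(is(db, "LigandReceptorDB"))
    if (!length(secretedGenes(db)))
        stop("empty ligand-receptor database")
    pos <- markers[markers$log_fc > 0, , drop = FALSE]
    groups <- sort(unique(markers$group))
    out <- lapply(groups, function(g) {
        sort(intersect(pos$gene[pos$group == g], secretedGenes(db)))
    })
    names(out) <- groups
    out
}

#' Extract candidate receptors per group from cluster markers
#'
#' Receptor eligibility mirrors ligand extraction: a receptor is eligible
#' for a receiver group when it is one of that group's positive markers
#' and a database receptor gene.
#'
#' @inheritParams extractClusterLigands
#' @return named list, group -> sorted receptor gene set.
#' @export
extractClusterReceptors <- function(markers, db) {
    stopifnot(is(db, "LigandReceptorDB"))
    if (!length(receptorGenes(db)))
        stop("empty ligand-receptor database")
    pos <- markers[markers$log_fc > 0, , drop = FALSE]
    groups <- sort(unique(markers$group))
    out <- lapply(groups, function(g) {
        sort(intersect(pos$gene[pos$group == g], receptorGenes(db)))
    })
    names(out) <- groups
    out
}

#' Secreting capacity of each group
#'
#' For every gene in the union of the group-specific ligand sets, the
#' per-group mean expression is z-scored across groups (sample s.d.; a
#' gene with zero across-group s.d. contributes 0). Each group's capacity
#' is the sum of z-scores over its own specific ligand set; groups are
#' ranked by capacity, descending.
#'
#' @param sce expression source as in [findAllMarkers()].
#' @param groups per-cell group labels (NA ignored); >= 2 groups required.
#' @param ligandSets named list, group -> specific ligand genes.
#' @return data.frame \code{group}, \code{n_ligands}, \code{capacity},
#'   \code{rank}, ordered by rank; the across-group z-score matrix is
#'   attached as attribute \code{"zscores"}.
#' @export
secretingCapacity <- function(sce, groups, ligandSets) {
    m <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    groups <- as.character(groups)
    lv <- sort(unique(groups[!is.na(groups)]))
    if (length(lv) < 2L) stop("need >= 2 groups")
    genes <- sort(unique(unlist(ligandSets)))
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
        message("ligand gene(s) absent from the matrix, skipped: ",
                paste(missing, collapse = ", "))
        genes <- setdiff(genes, missing)
    }
    z <- matrix(0, length(genes), length(lv), dimnames = list(genes, lv))
    if (length(genes)) {
        gm <- .groupMeans(m[genes, , drop = FALSE], groups)[, lv, drop = FALSE]
        gm <- matrix(gm, nrow = length(genes), dimnames = list(genes, lv))
        mu <- rowMeans(gm)
        s <- sqrt(.rowVars(gm))
        ok <- !is.na(s) & s > 0
        z[ok, ] <- (gm[ok, , drop = FALSE] - mu[ok]) / s[ok]
    }
    capacity <- vapply(lv, function(g) {
        own <- intersect(ligandSets[[g]], genes)
        if (length(own)) sum(z[own, g]) else 0
    }, numeric(1))
    nLig <- vapply(lv, function(g) length(intersect(ligandSets[[g]], genes)),
                   integer(1))
    out <- data.frame(group = lv, n_ligands = nLig, capacity = capacity,
                      rank = rank(-capacity, ties.method = "min"),
                      stringsAsFactors = FALSE)
    out <- out[order(out$rank, out$group), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "zscores") <- z
    out
}

#' Cross-match group ligands against trajectory-state biology
#'
#' A group's ligand is kept for a trajectory state iff the ligand's GO
#' terms intersect the state's enriched term set; the matched
#' (ligand, term) pairs are recorded. The per-(group, state) pair count
#' and distinct-ligand count are both emitted.
#'
#' @param ligandSets named list, group -> ligand genes.
#' @param annotation two-column data.frame (\code{gene}, \code{term}).
#' @param stateTerms named list, state -> enriched terms (a character
#'   vector or an enrichment result with a \code{term} column).
#' @return list with \code{matches} (data.frame \code{group},
#'   \code{state}, \code{ligand}, \code{term}), \code{pairCounts} and
#'   \code{ligandCounts} (group x state matrices), and \code{groupTotals}
#'   (pair counts summed over states).
#' @export
crossmatchLigands <- function(ligandSets, annotation, stateTerms) {
    ann <- unique(annotation[, 1:2])
    names(ann) <- c("gene", "term")
    stateTerms <- lapply(stateTerms, function(s) {
        if (is.data.frame(s)) unique(as.character(s$term))
        else unique(as.character(s))
    })
    groups <- names(ligandSets)
    states <- names(stateTerms)
    matches <- list()
    for (g in groups) {
        for (lig in ligandSets[[g]]) {
            terms <- ann$term[ann$gene == lig]
            if (!length(terms)) {
                message("ligand without annotation, treated as zero terms: ",
                        lig)
                next
            }
            for (s in states) {
                hit <- intersect(terms, stateTerms[[s]])
                if (length(hit))
                    matches[[length(matches) + 1L]] <- data.frame(
                        group = g, state = s, ligand = lig, term = hit,
                        stringsAsFactors = FALSE)
            }
        }
    }
    matches <- if (length(matches)) do.call(rbind, matches)
               else data.frame(group = character(), state = character(),
                               ligand = character(), term = character(),
                               stringsAsFactors = FALSE)
    pairCounts <- matrix(0L, length(groups), length(states),
                         dimnames = list(groups, states))
    ligandCounts <- pairCounts
    for (g in groups) for (s in states) {
        sub <- matches[matches$group == g & matches$state == s, , drop = FALSE]
        pairCounts[g, s] <- nrow(sub)
        ligandCounts[g, s] <- length(unique(sub$ligand))
    }
    list(matches = matches, pairCounts = pairCounts,
         ligandCounts = ligandCounts, groupTotals = rowSums(pairCounts))
}

#' Product-of-means ligand-receptor interaction scoring
#'
#' For every database pair (L, R), every sender group whose ligand set
#' contains L and every receiver group whose receptor set contains R, the
#' interaction score is the product of the mean expression of L over the
#' sender group's cells and the mean expression of R over the receiver
#' group's cells (natural-log normalized scale). Database genes absent
#' from the matrix are skipped with a message.
#'
#' @param sce expression source as in [findAllMarkers()].
#' @param groups per-cell group labels (NA ignored).
#' @param db a [LigandReceptorDB-class].
#' @param ligandSets named list, sender group -> eligible ligands.
#' @param receptorSets named list, receiver group -> eligible receptors.
#' @param excludeSelf skip sender-receiver combinations with identical
#'   group labels?
#' @return data.frame \code{sender}, \code{receiver}, \code{ligand},
#'   \code{receptor}, \code{score}, ordered by decreasing score.
#' @export
scoreLRPairs <- function(sce, groups, db, ligandSets, receptorSets,
                         excludeSelf = TRUE) {
    stopifnot(is(db, "LigandReceptorDB"))
    m <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    groups <- as.character(groups)
    pairs <- lrPairs(db)
    dbGenes <- unique(c(pairs$ligand, pairs$receptor))
    absent <- setdiff(dbGenes, rownames(m))
    if (length(absent))
        message("database gene(s) absent from the matrix, pairs skipped: ",
                paste(absent, collapse = ", "))
    present <- intersect(dbGenes, rownames(m))
    gm <- if (length(present))
        .groupMeans(m[present, , drop = FALSE], groups) else
        matrix(0, 0, 0)
    rows <- list()
    for (s in names(ligandSets)) {
        for (r in names(receptorSets)) {
            if (excludeSelf && s == r) next
            cand <- pairs[pairs$ligand %in% ligandSets[[s]] &
                          pairs$receptor %in% receptorSets[[r]] &
                          pairs$ligand %in% present &
                          pairs$receptor %in% present, , drop = FALSE]
            if (!nrow(cand)) next
            rows[[length(rows) + 1L]] <- data.frame(
                sender = s, receiver = r, ligand = cand$ligand,
                receptor = cand$receptor,
                score = gm[cand$ligand, s] * gm[cand$receptor, r],
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(sender = character(), receiver = character(),
                           ligand = character(), receptor = character(),
                           score = numeric(), stringsAsFactors = FALSE)
    out <- out[order(-out$score, out$sender, out$receiver, out$ligand), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Count scored pairs per sender-receiver combination
#'
#' @param table an interaction score table from [scoreLRPairs()].
#' @param minScore count rows with score strictly above this.
#' @return data.frame \code{sender}, \code{receiver}, \code{n_pairs},
#'   ordered by decreasing count.
#' @export
countPairsPerGroup <- function(table, minScore = 0) {
    if (!nrow(table))
        return(data.frame(sender = character(), receiver = character(),
                          n_pairs = integer(), stringsAsFactors = FALSE))
    sub <- table[table$score > minScore, , drop = FALSE]
    combos <- unique(table[, c("sender", "receiver")])
    n <- vapply(seq_len(nrow(combos)), function(i) {
        sum(sub$sender == combos$sender[i] & sub$receiver == combos$receiver[i])
    }, integer(1))
    out <- data.frame(sender = combos$sender, receiver = combos$receiver,
                      n_pairs = n, stringsAsFactors = FALSE)
    out <- out[order(-out$n_pairs, out$sender, out$receiver), , drop = FALSE]
    rownames(out) <- NULL
    out
}
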