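## Pathway over-representation and topology impact: hypergeometric
## enrichment of matched compounds, Holm / BH adjustment, and an impact
## score defined as the hit share of relative betweenness centrality.

#' Read a pathway library from JSON
#'
#' Format: \code{{"pathways": [{"name": ..., "compounds": [...],
#' "edges": [[a, b], ...]}, ...]}}. The compound universe is the union of
#' all compounds in the library — the reference-metabolome scope of the
#' over-representation test.
#'
#' @param path JSON file; defaults to the bundled synthetic library.
#' @return a \linkS4class{PathwayLibrary}.
#' @export
readPathwayLibrary <- function(path = system.file("extdata",
    "pathway_library_synthetic.json", package = "matchedMetabo")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$pathways) || !length(raw$pathways))
    stop("config error: empty pathway library")
  pathways <- lapply(raw$pathways, function(pw) {
    edges <- if (length(pw$edges)) {
      do.call(rbind, lapply(pw$edges, function(e) c(e[[1]], e[[2]])))
    } else matrix(character(0), 0, 2)
    list(name = pw$name, compounds = unlist(pw$compounds), edges = edges)
  })
  universe <- unique(unlist(lapply(pathways, `[[`, "compounds")))
  methods::new("PathwayLibrary", pathways = pathways, universe = universe)
}

#' Map significant features onto pathway compound sets
#'
#' Lipid main fractions and lipoprotein subfractions are excluded by
#' family (they have no direct compound match); remaining features without
#' a \code{compound_id} are reported as unmapped.
#'
#' @param significantFeatures data.frame (or DataFrame) with columns
#'   \code{family} and \code{compound_id} and feature names as rownames or
#'   a \code{feature} column; alternatively a character vector of compound
#'   identifiers (all treated as mapped metabolites).
#' @param library a \linkS4class{PathwayLibrary}.
#' @return list with \code{hits} (named list: pathway -> matched compound
#'   ids), \code{mapped} (compound ids used), \code{unmapped} (features
#'   without identifier), \code{excluded_by_family} (lipid features
#'   dropped).
#' @export
mapHits <- function(significantFeatures, library) {
  if (is.character(significantFeatures)) {
    mapped <- unique(significantFeatures)
    unmapped <- character(0); excluded <- character(0)
  } else {
    df <- as.data.frame(significantFeatures)
    feat_names <- if ("feature" %in% colnames(df)) df$feature
                  else rownames(df)
    lipid <- df$family %in% c("lipid_main_fraction",
                              "lipoprotein_subfraction")
    excluded <- feat_names[lipid]
    df <- df[!lipid, , drop = FALSE]
    feat_names <- feat_names[!lipid]
    has_id <- !is.na(df$compound_id) & nzchar(df$compound_id)
    unmapped <- feat_names[!has_id]
    mapped <- unique(df$compound_id[has_id])
  }
  in_universe <- intersect(mapped, library@universe)
  hits <- lapply(library@pathways, function(pw)
    intersect(pw$compounds, in_universe))
  names(hits) <- vapply(library@pathways, `[[`, character(1), "name")
  list(hits = hits, mapped = in_universe,
       unmapped = c(unmapped, setdiff(mapped, library@universe)),
       excluded_by_family = excluded)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' \eqn{P(X \ge \mathrm{hits})} when \code{nMappedInput} compounds are
#' drawn without replacement from a universe of \code{universeSize} of
#' which \code{totalCmpd} belong to the pathway.
#'
#' @param hits matched compounds in the pathway.
#' @param totalCmpd pathway compound count.
#' @param nMappedInput mapped input compounds.
#' @param universeSize reference universe size.
#' @return the raw enrichment p-value.
#' @export
oraHypergeometric <- function(hits, totalCmpd, nMappedInput, universeSize) {
  if (hits > min(totalCmpd, nMappedInput) || totalCmpd > universeSize ||
      nMappedInput > universeSize || any(c(hits, totalCmpd, nMappedInput,
                                           universeSize) < 0))
    stop("parameter error: inconsistent hypergeometric counts")
  phyper(hits - 1, m = totalCmpd, n = universeSize - totalCmpd,
         k = nMappedInput, lower.tail = FALSE)
}

#' Holm and Benjamini-Hochberg adjustment of pathway p-values
#'
#' @param rawPs numeric vector of raw p-values in [0, 1].
#' @return list with \code{holm_p} and \code{fdr_p}, both monotonized and
#'   capped at 1, in the input order.
#' @export
adjustPathwayP <- function(rawPs) {
  if (any(rawPs < 0 | rawPs > 1, na.rm = TRUE))
    stop("parameter error: p-values must lie in [0, 1]")
  list(holm_p = p.adjust(rawPs, method = "holm"),
       fdr_p = p.adjust(rawPs, method = "BH"))
}

#' Topology impact of a hit set within a pathway
#'
#' Relative betweenness centrality is computed per compound on the
#' undirected unit-weight pathway graph (normalized by
#' \eqn{(n-1)(n-2)/2}); the impact is the hit share of the total
#' centrality. When every betweenness is zero (e.g. at most 2 nodes) the
#' fallback is degree centrality; with no edges at all the share of nodes
#' is used. The result always lies in [0, 1].
#'
#' @param edges 2-column character matrix of undirected compound pairs.
#' @param compounds all pathway compounds (isolated nodes included).
#' @param hitSet compounds matched in the pathway.
#' @return the impact value.
#' @export
pathwayImpact <- function(edges, compounds, hitSet) {
  if (!all(hitSet %in% compounds))
    stop("parameter error: hit compound(s) not in the pathway")
  if (!length(hitSet)) return(0)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = compounds))
  cent <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  cent[!is.finite(cent)] <- 0   # degenerate normalization on tiny graphs
  if (sum(cent) == 0) {
    cent <- igraph::degree(g, normalized = TRUE)
    cent[!is.finite(cent)] <- 0
    if (sum(cent) == 0) cent <- setNames(rep(1, length(compounds)),
                                         compounds)
  }
  unname(sum(cent[hitSet]) / sum(cent))
}

#' Run the full pathway impact analysis
#'
#' Maps the significant compounds onto the library, computes per pathway
#' the hypergeometric enrichment p-value (against the library-universe
#' reference), Holm and BH adjustments, and the topology impact; pathways
#' with impact strictly above the threshold are flagged as considered.
#'
#' @inheritParams mapHits
#' @param impactThreshold impact cut-off (default 0.2).
#' @return data.frame sorted by raw p-value with columns \code{name},
#'   \code{total_cmpd}, \code{hits}, \code{raw_p}, \code{holm_p},
#'   \code{fdr_p}, \code{impact}, \code{considered}.
#' @export
runPathwayAnalysis <- function(significantFeatures,
                               library = readPathwayLibrary(),
                               impactThreshold = 0.2) {
  if (!length(library@pathways))
    stop("config error: empty pathway library")
  mh <- mapHits(significantFeatures, library)
  n_input <- length(mh$mapped)
  uni <- length(library@universe)
  rows <- lapply(seq_along(library@pathways), function(i) {
    pw <- library@pathways[[i]]
    hit_set <- mh$hits[[pw$name]]
    data.frame(name = pw$name, total_cmpd = length(pw$compounds),
               hits = length(hit_set),
               raw_p = oraHypergeometric(length(hit_set),
                                         length(pw$compounds),
                                         n_input, uni),
               impact = pathwayImpact(pw$edges, pw$compounds, hit_set),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  adj <- adjustPathwayP(res$raw_p)
  res$holm_p <- adj$holm_p
  res$fdr_p <- adj$fdr_p
  res$considered <- res$impact > impactThreshold
  res <- res[order(res$raw_p), c("name", "total_cmpd", "hits", "raw_p",
                                 "holm_p", "fdr_p", "impact", "considered")]
  rownames(res) <- NULL
  res
}
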