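#' Build the bipartite drug/animal-model network
#'
#' Links approved drugs to the animal models they were tested against:
#' a drug node and a model node are connected if and only if the drug was
#' tested in at least `min_assays` distinct assays whose description
#' mentions the model, with that count as the edge weight. General-purpose
#' strains (outbred stocks screened indiscriminately across indications,
#' e.g. Wistar rat, Swiss mouse) are excluded so the model side keeps only
#' strains that spontaneously develop disease-related phenotypes, plus
#' induced and transgenic models. Synonymous experimental-model names are
#' consolidated through an editable merge map before counting. Isolated
#' nodes are dropped.
#'
#' @param mentions mention table from [annotate_corpus()].
#' @param assays assay table.
#' @param compounds compound table (`max_phase` identifies approved drugs).
#' @param links optional assay-compound link table.
#' @param min_assays edge threshold (default 5).
#' @param exclusions character vector of normalized model names to exclude.
#' @param merges named character vector mapping synonym -> canonical model
#'   name (e.g. `c("maximum electric shock" = "maximal electroshock",
#'   "hotplate" = "hot plate")`).
#' @return igraph object with vertex attributes `type` (`FALSE` = drug,
#'   `TRUE` = model), `kind` ("drug" or the entity class), `n_assays`, and
#'   for drugs `atc_level2`; edge attribute `weight` = shared assay count.
#' @export
build_network <- function(mentions, assays, compounds, links = NULL,
                          min_assays = 5L, exclusions = character(),
                          merges = character()) {
  model_classes <- c("genetic_strain", "experimental_model", "transgenic_model")
  m <- mentions[mentions$entity_class %in% model_classes, , drop = FALSE]
  if (nrow(m) && length(merges)) {
    hit <- m$normalized %in% names(merges)
    m$normalized[hit] <- unname(merges[m$normalized[hit]])
  }
  if (nrow(m) && length(exclusions)) {
    m <- m[!m$normalized %in% exclusions, , drop = FALSE]
  }
  appr <- compounds[compounds$max_phase == 4L, , drop = FALSE]
  ac <- vm_assay_compounds(assays, links)
  # assay -> approved drugs tested in it
  drug_assay <- do.call(rbind, lapply(seq_len(nrow(assays)), function(i) {
    cids <- intersect(ac[[i]], appr$compound_id)
    if (!length(cids)) return(NULL)
    data.frame(assay_id = assays$assay_id[i], compound_id = cids,
               stringsAsFactors = FALSE)
  }))
  g_empty <- igraph::make_empty_graph(directed = FALSE)
  if (is.null(drug_assay) || !nrow(m)) return(g_empty)
  model_assay <- unique(m[, c("assay_id", "normalized", "entity_class")])
  pairs <- merge(drug_assay, model_assay, by = "assay_id")
  if (!nrow(pairs)) return(g_empty)
  key <- paste(pairs$compound_id, pairs$normalized, sep = "\r")
  cnt <- tapply(pairs$assay_id, key, function(x) length(unique(x)))
  keep <- cnt >= min_assays
  if (!any(keep)) return(g_empty)
  parts <- strsplit(names(cnt)[keep], "\r", fixed = TRUE)
  edges <- data.frame(drug = vapply(parts, `[`, "", 1),
                      model = vapply(parts, `[`, "", 2),
                      weight = as.integer(cnt[keep]), stringsAsFactors = FALSE)
  drug_names <- sort(unique(edges$drug))
  model_names <- sort(unique(edges$model))
  # node sizes: distinct assays involving the drug / the model
  drug_sizes <- tapply(drug_assay$assay_id, drug_assay$compound_id,
                       function(x) length(unique(x)))
  model_sizes <- tapply(model_assay$assay_id, model_assay$normalized,
                        function(x) length(unique(x)))
  model_kind <- model_assay$entity_class[match(model_names, model_assay$normalized)]
  atc2 <- vapply(drug_names, function(d) {
    codes <- unlist(appr$atc_codes[appr$compound_id == d], use.names = FALSE)
    l2 <- vm_atc_level2(codes)
    if (length(l2)) paste(sort(l2), collapse = ";") else ""
  }, "")
  # drug display name when available
  dn <- appr$name[match(drug_names, appr$compound_id)]
  verts <- data.frame(
    name = c(drug_names, model_names),
    type = c(rep(FALSE, length(drug_names)), rep(TRUE, length(model_names))),
    kind = c(rep("drug", length(drug_names)), model_kind),
    n_assays = c(as.integer(drug_sizes[drug_names]),
                 as.integer(model_sizes[model_names])),
    atc_level2 = c(atc2, rep("", length(model_names))),
    label = c(ifelse(is.na(dn), drug_names, dn), model_names),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    edges[, c("drug", "model", "weight")], directed = FALSE, vertices = verts)
}

#' Export / import the drug-model network
#'
#' Writes the attributed graph as GraphML or GML (via igraph) or a TSV edge
#' list; `read_network` restores GraphML/GML exports for round-tripping.
#'
#' @param graph igraph object from [build_network()].
#' @param path output file.
#' @param format `"graphml"`, `"gml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("graphml", "gml", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    e <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(e, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    if (format == "gml" && igraph::vcount(graph) > 0) {
      # GML has no boolean type; write the bipartite flag as 0/1
      for (a in igraph::vertex_attr_names(graph)) {
        v <- igraph::vertex_attr(graph, a)
        if (is.logical(v)) graph <- igraph::set_vertex_attr(graph, a,
                                                            value = as.integer(v))
      }
    }
    igraph::write_graph(graph, path, format = format)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  igraph::read_graph(path, format = format)
}

#' Structural checks on a built network
#'
#' @param graph igraph object.
#' @return `TRUE` if the graph is bipartite with edges only between drug
#'   and model nodes; otherwise an error.
#' @export
check_bipartite <- function(graph) {
  if (igraph::vcount(graph) == 0) return(TRUE)
  tp <- igraph::V(graph)$type
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) && any(tp[el[, 1]] == tp[el[, 2]])) {
    stop("network is not bipartite: edge within one node class")
  }
  TRUE
}
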