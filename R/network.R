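#' Build a taxon co-occurrence graph from mined networks
#'
#' Every record of layer >= 2 in the requested direction increments, for each
#' unordered pair of taxa it contains, the weight of the edge joining them;
#' layer-1 records contribute isolated nodes. Each node gets an
#' `abundance_class`: "high" when its modal bin across contributing records
#' lies in `high_bins`, "low" for `low_bins`, otherwise "other" (ties between
#' classes also give "other").
#'
#' @param networks a `mined_networks` object.
#' @param direction "case-enriched" or "control-enriched".
#' @param high_bins,low_bins bin sets defining the node classes (the study
#'   called bins 7-9 highly abundant and 1-3 little abundant).
#' @return an igraph graph with vertex attributes `name`, `abundance_class`
#'   and edge attribute `weight`; scope recorded in graph attribute
#'   `direction`.
#' @export
build_graph <- function(networks, direction = "case-enriched",
                        high_bins = 7:9, low_bins = 1:3) {
  recs <- as.data.frame(networks)
  recs <- recs[recs$direction == direction, , drop = FALSE]
  if (nrow(recs) == 0) stop("no records for direction ", direction)
  bins_by_taxon <- list()
  edge_w <- new.env(hash = TRUE)
  for (i in seq_len(nrow(recs))) {
    pr <- parse_pairs(recs$pairs[i])
    for (j in seq_len(nrow(pr)))
      bins_by_taxon[[pr$feature[j]]] <-
        c(bins_by_taxon[[pr$feature[j]]], pr$bin[j])
    if (nrow(pr) >= 2) {
      cmb <- utils::combn(sort(pr$feature), 2)
      for (k in seq_len(ncol(cmb))) {
        key <- paste(cmb[1, k], cmb[2, k], sep = "\t")
        edge_w[[key]] <- (if (is.null(edge_w[[key]])) 0 else edge_w[[key]]) + 1
      }
    }
  }
  taxa <- sort(names(bins_by_taxon))
  cls <- vapply(taxa, function(t) {
    b <- bins_by_taxon[[t]]
    tb <- table(b)
    modal <- as.integer(names(tb)[tb == max(tb)])
    in_high <- modal %in% high_bins; in_low <- modal %in% low_bins
    if (any(in_high) && !any(in_low) && all(in_high)) "high"
    else if (any(in_low) && !any(in_high) && all(in_low)) "low"
    else "other"
  }, character(1))
  keys <- ls(edge_w)
  if (length(keys)) {
    ep <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    g <- igraph::graph_from_data_frame(
      data.frame(from = ep[, 1], to = ep[, 2],
                 weight = vapply(keys, function(k) edge_w[[k]], numeric(1))),
      directed = FALSE, vertices = data.frame(name = taxa))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(taxa)
  }
  igraph::V(g)$abundance_class <- cls[match(igraph::V(g)$name, taxa)]
  igraph::graph_attr(g, "direction") <- direction
  g
}

#' Differential representation of taxa between case- and control-derived
#' networks
#'
#' For each taxon appearing in either direction's mined records, a
#' two-proportion z test compares its representation among case-enriched
#' versus control-enriched output. `basis = "records"` counts records
#' containing the taxon out of all records in that direction;
#' `basis = "animals"` counts case animals carrying at least one record that
#' contains the taxon out of all cases (and likewise controls). Raw p-values
#' are reported alongside Benjamini-Hochberg adjusted ones; the significance
#' flag uses the adjusted value.
#'
#' @param networks_case,networks_control significant records
#'   (`mined_networks` objects or their data.frames) for the two directions.
#'   Typically both come from one [mine()] run, split by record direction.
#' @param basis "records" or "animals".
#' @param binned,labels required when `basis = "animals"` to recompute
#'   carriage.
#' @param alpha flag threshold on adjusted p.
#' @return data.frame: taxon, a, n1, c, n2, z, p, p_adjusted, flagged.
#' @export
taxon_enrichment <- function(networks_case, networks_control,
                             basis = c("records", "animals"),
                             binned = NULL, labels = NULL, alpha = 0.05) {
  basis <- match.arg(basis)
  rc <- if (inherits(networks_case, "mined_networks"))
    as.data.frame(networks_case) else networks_case
  rk <- if (inherits(networks_control, "mined_networks"))
    as.data.frame(networks_control) else networks_control
  if (nrow(rc) == 0 || nrow(rk) == 0)
    stop("both directions must have at least one record")
  taxa_of <- function(df) lapply(df$pairs, function(p) parse_pairs(p)$feature)
  tc <- taxa_of(rc); tk <- taxa_of(rk)
  taxa <- sort(unique(c(unlist(tc), unlist(tk))))
  if (basis == "records") {
    n1 <- nrow(rc); n2 <- nrow(rk)
    a <- vapply(taxa, function(t) sum(vapply(tc, function(s) t %in% s,
                                             logical(1))), numeric(1))
    cc <- vapply(taxa, function(t) sum(vapply(tk, function(s) t %in% s,
                                              logical(1))), numeric(1))
  } else {
    stopifnot(!is.null(binned), !is.null(labels))
    lab <- labels$label[match(rownames(binned$codes), labels$animal_id)]
    case_ids <- rownames(binned$codes)[!is.na(lab) & lab == "case"]
    ctrl_ids <- rownames(binned$codes)[!is.na(lab) & lab == "control"]
    n1 <- length(case_ids); n2 <- length(ctrl_ids)
    carrier_union <- function(df, sel, ids) {
      hit <- rep(FALSE, length(ids))
      for (i in which(sel)) {
        cs <- carriers(binned, parse_pairs(df$pairs[i]))
        hit <- hit | ids %in% cs
      }
      sum(hit)
    }
    a <- vapply(taxa, function(t) carrier_union(
      rc, vapply(tc, function(s) t %in% s, logical(1)), case_ids), numeric(1))
    cc <- vapply(taxa, function(t) carrier_union(
      rk, vapply(tk, function(s) t %in% s, logical(1)), ctrl_ids), numeric(1))
  }
  z <- mapply(function(ai, ci) two_proportion_z(ai, n1, ci, n2)$z, a, cc)
  p <- 2 * stats::pnorm(-abs(z))
  p[z == 0] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(taxon = taxa, a = a, n1 = n1, c = cc, n2 = n2, z = z, p = p,
             p_adjusted = padj, flagged = padj <= alpha & z != 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
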