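#' Read gene models with exon records
#'
#' Loads gene models into the internal exon table used by
#' [window_gene_links()]: one row per exon with columns `gene_id`, `symbol`,
#' `arm`, `strand`, `start`, `end`, `coding`. Coordinates are normalised to
#' 0-based half-open internally; GFF3 input (1-based closed) is shifted,
#' BED and TSV input pass through unchanged. In GFF3 input, rows of type
#' `exon` become noncoding exon records and rows of type `CDS` become coding
#' ones; the gene identifier is taken from the `gene_id` attribute, else
#' from `Parent`. A TSV input must already carry the internal columns.
#'
#' @param path Input path.
#' @param format `"gff3"`, `"bed"` (BED6, all exons flagged coding) or
#'   `"tsv"`.
#' @return A tibble of exon records sorted by arm and start.
#' @export
read_gene_models <- function(path, format = c("gff3", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package")
    }
    g <- rtracklayer::import(path, format = "gff3")
    g <- g[as.character(g$type) %in% c("exon", "CDS")]
    meta <- as.data.frame(g)
    gene_id <- if ("gene_id" %in% names(meta)) {
      as.character(meta$gene_id)
    } else {
      vapply(meta$Parent, function(p) as.character(p)[1], character(1))
    }
    symbol <- if ("Name" %in% names(meta)) as.character(meta$Name) else gene_id
    exons <- tibble(
      gene_id = gene_id,
      symbol = symbol,
      arm = as.character(meta$seqnames),
      strand = as.character(meta$strand),
      start = meta$start - 1,  # 1-based closed -> 0-based half-open
      end = meta$end,
      coding = as.character(meta$type) == "CDS"
    )
  } else if (format == "bed") {
    x <- readr::read_tsv(path, col_names = c("arm", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE, progress = FALSE)
    exons <- tibble(gene_id = x$name, symbol = x$name, arm = x$arm,
                    strand = x$strand, start = x$start, end = x$end,
                    coding = TRUE)
  } else {
    exons <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    check_columns(exons, c("gene_id", "arm", "start", "end", "coding"),
                  "exon table")
    if (!"symbol" %in% names(exons)) exons$symbol <- exons$gene_id
    if (!"strand" %in% names(exons)) exons$strand <- "*"
  }
  if (any(exons$start >= exons$end)) {
    abort("exon start must be < end after coordinate normalisation")
  }
  arrange(as_tibble(exons), .data$arm, .data$start, .data$end)
}

#' Link genes to genomic windows via exon overlap and nearest exons
#'
#' A gene is linked to a window if (i) one of its qualifying exons overlaps
#' the window (half-open interval intersection), or (ii) a qualifying exon
#' of that gene is the nearest exon strictly to the left of the window
#' start, or (iii) the nearest strictly to the right of the window end --
#' the flanking rules account for potential regulatory regions. "Nearest"
#' means the minimal bp gap among all genes' qualifying exons on that side;
#' distance ties link all tied genes. With `mode = "any_exon"` every exon
#' qualifies (coding or noncoding); with `mode = "coding_exon"` (used for
#' differentiation-outlier windows) only coding exons qualify. Strand is
#' carried but never conditions the rules. Both overlapping and flanking
#' links are reported, with distinct link types.
#'
#' @param windows Tibble with columns `window`, `arm`, `start`, `end`
#'   (0-based half-open).
#' @param genes Exon table from [read_gene_models()] (or
#'   [sim_gene_models()]).
#' @param mode `"any_exon"` or `"coding_exon"`.
#' @return A tibble with columns `window`, `gene_id`, `symbol`, `link_type`
#'   (`overlap`, `nearest_left`, `nearest_right`) and `distance` (bp gap; 0
#'   for overlaps). Windows on arms without genes yield no rows and a
#'   warning.
#' @export
window_gene_links <- function(windows, genes,
                              mode = c("any_exon", "coding_exon")) {
  mode <- match.arg(mode)
  check_columns(windows, c("window", "arm", "start", "end"), "windows")
  exons <- if (mode == "coding_exon") genes[genes$coding, ] else genes
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    ex <- exons[exons$arm == w$arm, ]
    if (nrow(ex) == 0) {
      warn(sprintf("window %s: no genes on arm %s", w$window, w$arm))
      return(tibble(window = character(), gene_id = character(),
                    symbol = character(), link_type = character(),
                    distance = numeric()))
    }
    ov <- ex[ex$start < w$end & ex$end > w$start, ]
    links <- tibble(window = as.character(w$window),
                    gene_id = unique(ov$gene_id)) %>%
      left_join(distinct(ex[c("gene_id", "symbol")]), by = "gene_id") %>%
      mutate(link_type = "overlap", distance = 0)
    left <- ex[ex$end <= w$start, ]
    if (nrow(left) > 0) {
      gap <- w$start - left$end
      best <- left[gap == min(gap), ]
      links <- bind_rows(links, tibble(
        window = as.character(w$window),
        gene_id = unique(best$gene_id),
        symbol = best$symbol[match(unique(best$gene_id), best$gene_id)],
        link_type = "nearest_left", distance = min(gap)
      ))
    }
    right <- ex[ex$start >= w$end, ]
    if (nrow(right) > 0) {
      gap <- right$start - w$end
      best <- right[gap == min(gap), ]
      links <- bind_rows(links, tibble(
        window = as.character(w$window),
        gene_id = unique(best$gene_id),
        symbol = best$symbol[match(unique(best$gene_id), best$gene_id)],
        link_type = "nearest_right", distance = min(gap)
      ))
    }
    links
  })
}

#' Read a gene list (one identifier per line)
#'
#' @param path Plain-text file of gene identifiers.
#' @return A character vector.
#' @export
read_gene_list <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Flag linked genes against curated candidate lists
#'
#' Marks every linked gene with one boolean column per supplied list (e.g.
#' curated male-mating-behaviour, wing-development or nervous-system gene
#' sets), and flags genes linked to any differentiation-outlier window as
#' `differentiation_outlier`. List entries that match no linked gene are
#' ignored with a warning.
#'
#' @param links Output of [window_gene_links()].
#' @param lists Named list of character vectors of gene ids (see
#'   [read_gene_list()]).
#' @param outlier_windows Optional character vector of window ids that are
#'   population-genetic outliers.
#' @return `links` with one logical column per list plus
#'   `differentiation_outlier`.
#' @export
flag_candidates <- function(links, lists = list(), outlier_windows = NULL) {
  out <- links
  for (nm in names(lists)) {
    ids <- lists[[nm]]
    unknown <- setdiff(ids, links$gene_id)
    if (length(unknown) > 0) {
      warn(sprintf("list '%s': %d id(s) match no linked gene", nm,
                   length(unknown)))
    }
    out[[nm]] <- out$gene_id %in% ids
  }
  out$differentiation_outlier <- if (is.null(outlier_windows)) {
    FALSE
  } else {
    hits <- unique(out$gene_id[out$window %in% as.character(outlier_windows)])
    out$gene_id %in% hits
  }
  out
}
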