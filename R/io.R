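#' Read a gene-by-sample expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells must be numeric. Tab and comma delimiters
#' are auto-detected from the header line (or forced via `sep`). Lines
#' starting with `#` are ignored, so artifacts written by this package (which
#' carry a config-hash comment) round-trip.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `NULL` (default) auto-detects `\t` vs `,`.
#' @return Numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty expression file: ", path)
  if (is.null(sep)) {
    header <- lines[1]
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  df <- utils::read.table(path,
    sep = sep, header = TRUE, check.names = FALSE,
    comment.char = "#", stringsAsFactors = FALSE, quote = "\""
  )
  if (nrow(df) < 2 || ncol(df) < 3) {
    stop("expression matrix in ", path, " needs >= 2 genes and >= 2 samples")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate gene identifiers in ", path, ": ", paste(dups, collapse = ", "))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(
        "non-numeric value ", dQuote(col[bad]), " at data row ", bad,
        " (gene ", ids[bad], "), column ", dQuote(names(vals)[j])
      )
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1]
      stop("NA value at data row ", bad, " (gene ", ids[bad], "), column ",
        dQuote(names(vals)[j]))
    }
  }
  E <- as.matrix(vals)
  storage.mode(E) <- "double"
  rownames(E) <- ids
  as_expression_values(E)
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param E Numeric matrix with rownames (gene ids) and colnames.
#' @param path Output path.
#' @param id_column Name of the gene-id column in the header.
#' @param comment Optional comment line(s) written (prefixed `# `) before the
#'   header.
#' @export
write_expression <- function(E, path, id_column = "gene_id", comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c(id_column, colnames(E)), collapse = "\t"), con)
  utils::write.table(E, con,
    sep = "\t", quote = FALSE, col.names = FALSE,
    row.names = TRUE
  )
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every knob of the transform/cluster/map/neighbors workflow into a
#' single validated object. The configuration is serialized verbatim into
#' every output artifact (as an md5 hash comment plus a JSON sidecar), so a
#' replicated figure or table is a pure function of (input file, config).
#'
#' @param input Path to the input expression matrix (TSV/CSV), or `NULL` when
#'   `values` is supplied directly to [run_pipeline()].
#' @param measure Dissimilarity measure, see [pairwise_dissimilarity()].
#' @param algorithm `"icc"` or `"kmeans"`.
#' @param k Number of clusters.
#' @param ks Candidate map dimensions for [select_tsne_mcp_o()] (`NULL`:
#'   package default sweep).
#' @param seed Integer seed (k-means seeding and random t-SNE init).
#' @param perplexity t-SNE perplexity.
#' @param max_iter Clustering iteration cap.
#' @param tsne_iter t-SNE gradient-descent iterations.
#' @param tsne_init t-SNE initialization, `"pca"` (deterministic) or
#'   `"random"` (seeded); see [tsne_embed()].
#' @param out Output path prefix.
#' @param plot Whether to write a PNG map with neighbor edges.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, measure = "pcc-mcp", algorithm = c("icc", "kmeans"),
                       k = 4, ks = NULL, seed = 0, perplexity = 30,
                       max_iter = 100, tsne_iter = 1000, tsne_init = c("pca", "random"),
                       out = "mcpcluster_run", plot = FALSE) {
  algorithm <- match.arg(algorithm)
  measure <- match.arg(measure, MEASURES)
  tsne_init <- match.arg(tsne_init)
  stopifnot(k >= 2, perplexity > 0, max_iter >= 1, tsne_iter >= 50)
  structure(
    list(
      input = input, measure = measure, algorithm = algorithm, k = as.integer(k),
      ks = ks, seed = as.integer(seed), perplexity = perplexity,
      max_iter = as.integer(max_iter), tsne_iter = as.integer(tsne_iter),
      tsne_init = tsne_init, out = out, plot = isTRUE(plot)
    ),
    class = "run_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full transform / cluster / map / neighbors pipeline
#'
#' Reads an expression matrix, computes the pairwise dissimilarity under the
#' configured measure, clusters it ([icc_cluster()] or [kmeans_baseline()]),
#' sweeps silhouette-scored t-SNE maps to pick the optimal one
#' ([select_tsne_mcp_o()]), derives the nearest-neighbor edge list
#' ([neighbor_map()]), and writes:
#'
#' * `<out>_clusters.tsv` — gene_id, cluster
#' * `<out>_map.tsv` — gene_id, x, y, cluster (the chosen map)
#' * `<out>_selection.json` — (k, S) per candidate, chosen k, config, hash
#' * `<out>_neighbors.tsv` — gene_id, nearest_id, second_id
#' * `<out>_map.png` — optional scatter plot with neighbor edges
#'
#' Every artifact carries the md5 hash of the serialized config, so outputs
#' of deterministic stages are byte-identical across reruns of the same
#' config.
#'
#' @param config A [run_config()] object.
#' @param values Optional in-memory gene-by-sample matrix overriding
#'   `config$input`.
#' @return Invisibly, a list with the in-memory results (`dissimilarity`,
#'   `clustering`, `selection`, `neighbors`, `files`, `hash`).
#' @export
run_pipeline <- function(config, values = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  stage <- function(name, expr) {
    message("[", name, "] ", appendLF = FALSE)
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(format(round(as.numeric(Sys.time() - t0, units = "secs"), 2)), "s")
    res
  }

  E <- stage("read", {
    if (!is.null(values)) as_expression_values(values) else read_expression(config$input)
  })
  D <- stage("distances", pairwise_dissimilarity(E, config$measure))
  fit <- stage("cluster", {
    if (config$algorithm == "icc") {
      icc_cluster(D, config$k, max_iter = config$max_iter)
    } else {
      kmeans_baseline(E, config$k,
        measure = config$measure, seed = config$seed,
        max_iter = config$max_iter
      )
    }
  })
  sel <- stage("map", {
    T <- mcp_matrix(E)
    perp <- min(config$perplexity, floor((nrow(E) - 1) / 3))
    select_tsne_mcp_o(T, fit$labels,
      ks = config$ks, seed = config$seed,
      perplexity = perp, max_iter = config$tsne_iter, init = config$tsne_init
    )
  })
  nb <- stage("neighbors", neighbor_map(D))

  files <- stage("write", {
    prefix <- config$out
    dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
    cmt <- paste0("config ", hash)
    f_clusters <- paste0(prefix, "_clusters.tsv")
    writeLines(
      c(paste0("# ", cmt), "gene_id\tcluster",
        paste(rownames(E), fit$labels, sep = "\t")),
      f_clusters
    )
    f_map <- paste0(prefix, "_map.tsv")
    co <- sel$chosen_map$coords
    writeLines(
      c(paste0("# ", cmt), "gene_id\tx\ty\tcluster",
        paste(rownames(E), co[, 1], co[, 2], fit$labels, sep = "\t")),
      f_map
    )
    f_sel <- paste0(prefix, "_selection.json")
    jsonlite::write_json(
      list(
        candidates = sel$candidates, chosen_k = sel$chosen_k,
        algorithm = config$algorithm, measure = config$measure, k = config$k,
        seed = config$seed, medoid_ids = fit$medoid_ids,
        objective = fit$objective, iterations = fit$iterations,
        converged = fit$converged, config = unclass(config), config_md5 = hash
      ),
      f_sel,
      auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE
    )
    f_nb <- paste0(prefix, "_neighbors.tsv")
    writeLines(
      c(paste0("# ", cmt), "gene_id\tnearest_id\tsecond_id",
        paste(nb$gene_id, nb$nearest_id, nb$second_id, sep = "\t")),
      f_nb
    )
    out <- c(clusters = f_clusters, map = f_map, selection = f_sel, neighbors = f_nb)
    if (config$plot) {
      f_png <- paste0(prefix, "_map.png")
      grDevices::png(f_png, width = 1400, height = 1200, res = 150)
      plot(sel$chosen_map, labels = fit$labels, neighbors = nb,
        main = paste0("t-SNE-MCP-O (k = ", sel$chosen_k, ", ", config$measure, ")"))
      grDevices::dev.off()
      out <- c(out, plot = f_png)
    }
    out
  })

  invisible(list(
    dissimilarity = D, clustering = fit, selection = sel, neighbors = nb,
    files = files, hash = hash
  ))
}

#' Cross-tabulate two clusterings of the same genes
#'
#' Cluster labels are arbitrary, so clusterings at different `k` (or from
#' different runs) are compared by membership overlap, not label equality.
#' For each cluster of `sub` this reports the best-matching cluster of
#' `super` and the fraction of members shared with it — the per-sub-cluster
#' "sensitivity" used to assess the stability of a clustering when the
#' cluster count changes.
#'
#' @param super,sub Two label vectors over the same genes (e.g. a coarse and
#'   a fine clustering).
#' @return A data.frame with one row per `sub` cluster: `sub_cluster`,
#'   `size`, `best_super`, `overlap` (gene count), `sensitivity` (percent).
#' @export
cluster_consistency <- function(super, sub) {
  if (length(super) != length(sub)) stop("label vectors must have equal length")
  tab <- table(sub = sub, super = super)
  best <- apply(tab, 1, which.max)
  data.frame(
    sub_cluster = rownames(tab),
    size = as.integer(rowSums(tab)),
    best_super = colnames(tab)[best],
    overlap = as.integer(tab[cbind(seq_len(nrow(tab)), best)]),
    sensitivity = 100 * as.integer(tab[cbind(seq_len(nrow(tab)), best)]) /
      as.integer(rowSums(tab)),
    stringsAsFactors = FALSE
  )
}
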