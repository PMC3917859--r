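# Plain-text Purkinje network format (".ptree"):
#
#   ptree <n_nodes> <n_edges> <n_roots> <n_terminals> <n_pmjs>
#   nodes                 # then one line per node: id x y z on_surface
#   edges                 # then one line per edge: id n1 n2
#   roots                 # then one line: space-separated root node ids
#   terminals             # then one line: space-separated terminal node ids
#   pmjs                  # then one line per PMJ:
#                         #   terminal_id k R_MOhm loading_factor coupled_ids...
#
# Ids are 1-based; positions in mm; edge lengths are recomputed on read.

#' Write a Purkinje network (and optional PMJ set) as plain text
#'
#' @param network a [grow_network()] result.
#' @param path output file path.
#' @param pmjset optional [place_pmjs()] result to embed.
#' @export
write_ptree <- function(network, path, pmjset = NULL) {
  stopifnot(inherits(network, "purkinje_network"))
  n_pmj <- if (is.null(pmjset)) 0L else nrow(pmjset$pmjs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ptree %d %d %d %d %d", nrow(network$nodes),
                     nrow(network$edges), length(network$roots),
                     length(network$terminals), n_pmj), con)
  writeLines("nodes", con)
  writeLines(sprintf("%d %.17g %.17g %.17g %d", seq_len(nrow(network$nodes)),
                     network$nodes[, 1], network$nodes[, 2], network$nodes[, 3],
                     as.integer(network$on_surface)), con)
  writeLines("edges", con)
  writeLines(sprintf("%d %d %d", seq_len(nrow(network$edges)),
                     network$edges$n1, network$edges$n2), con)
  writeLines("roots", con)
  writeLines(paste(network$roots, collapse = " "), con)
  writeLines("terminals", con)
  writeLines(paste(network$terminals, collapse = " "), con)
  writeLines("pmjs", con)
  if (n_pmj > 0L) {
    for (i in seq_len(n_pmj)) {
      writeLines(paste(c(pmjset$pmjs$terminal_id[i],
                         length(pmjset$coupled[[i]]),
                         sprintf("%.17g", pmjset$pmjs$r_pmj[i]),
                         sprintf("%.17g", pmjset$pmjs$loading_factor[i]),
                         pmjset$coupled[[i]]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a plain-text Purkinje network
#'
#' @param path file written by [write_ptree()].
#' @return List with `network` (class `purkinje_network`) and `pmjset`
#'   (class `pmj_set`, or `NULL` if the file holds no PMJs).
#' @export
read_ptree <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "ptree") stop("not a ptree file")
  counts <- as.integer(hdr[-1])
  nn <- counts[1]; ne <- counts[2]; np <- counts[5]
  i <- which(lines == "nodes")[1]
  node_rows <- do.call(rbind, strsplit(lines[i + seq_len(nn)], " "))
  pos <- matrix(as.numeric(node_rows[, 2:4]), nn, 3)
  on_surface <- as.integer(node_rows[, 5]) == 1L
  i <- which(lines == "edges")[1]
  if (ne > 0L) {
    edge_rows <- do.call(rbind, strsplit(lines[i + seq_len(ne)], " "))
    n1 <- as.integer(edge_rows[, 2]); n2 <- as.integer(edge_rows[, 3])
  } else {
    n1 <- integer(0); n2 <- integer(0)
  }
  i <- which(lines == "roots")[1]
  roots <- as.integer(strsplit(lines[i + 1L], " ")[[1]])
  i <- which(lines == "terminals")[1]
  terminals <- as.integer(strsplit(trimws(lines[i + 1L]), " ")[[1]])
  terminals <- terminals[!is.na(terminals)]
  grown <- rep(TRUE, nn); grown[roots] <- FALSE
  len <- if (ne > 0L) sqrt(rowSums((pos[n2, , drop = FALSE] -
                                      pos[n1, , drop = FALSE])^2)) else numeric(0)
  network <- structure(list(nodes = pos, on_surface = on_surface, grown = grown,
                            edges = data.frame(n1 = n1, n2 = n2, length_mm = len),
                            roots = roots, terminals = terminals, rule = NULL),
                       class = "purkinje_network")
  pmjset <- NULL
  if (np > 0L) {
    i <- which(lines == "pmjs")[1]
    tid <- integer(np); rp <- numeric(np); lf <- numeric(np)
    coupled <- vector("list", np)
    for (j in seq_len(np)) {
      f <- strsplit(lines[i + j], " ")[[1]]
      tid[j] <- as.integer(f[1])
      k <- as.integer(f[2])
      rp[j] <- as.numeric(f[3]); lf[j] <- as.numeric(f[4])
      coupled[[j]] <- if (k > 0L) as.integer(f[4L + seq_len(k)]) else integer(0)
    }
    pmjset <- structure(list(pmjs = data.frame(terminal_id = tid, r_pmj = rp,
                                               loading_factor = lf),
                             coupled = coupled, min_distance = NA_real_,
                             rng_seed = NA_integer_,
                             insertion_depth_fraction = NA_real_),
                        class = "pmj_set")
  }
  list(network = network, pmjset = pmjset)
}
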