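#' Directed small-world topology with fixed in-degree
#'
#' Builds a directed ring lattice in which every neuron receives one edge from
#' each of its `in_degree` nearest ring neighbours (for odd `in_degree`,
#' `ceiling(in_degree/2)` clockwise and `floor(in_degree/2)` counter-clockwise
#' predecessors), then rewires the *source* of each incoming edge
#' independently with probability `rewire_prob` to a uniformly chosen
#' non-self, non-duplicate source. Rewiring the source rather than the target
#' preserves every neuron's in-degree exactly, which the mean-field update
#' rule assumes when it normalises local fields by the scalar in-degree `k`.
#'
#' @param n_neurons number of neurons `N`.
#' @param in_degree incoming degree `k` of every neuron (`0 < k < N`).
#' @param rewire_prob probability of rewiring each local edge (0 to 1).
#' @param seed optional integer seed; if supplied the construction is
#'   reproducible.
#' @return an object of class `cm_topology`: a list with elements `n_neurons`,
#'   `in_degree`, `rewire_prob`, and the edge list as integer vectors `src`
#'   and `tgt` (edge `src[e] -> tgt[e]`, 1-based).
#' @examples
#' top <- build_small_world(100, 6, 0.1, seed = 1)
#' table(tabulate(top$tgt, 100))  # every neuron has in-degree 6
#' @export
build_small_world <- function(n_neurons, in_degree, rewire_prob, seed = NULL) {
  n <- as.integer(n_neurons)
  k <- as.integer(in_degree)
  if (is.na(n) || n < 2L) stop("n_neurons must be an integer >= 2")
  if (is.na(k) || k < 1L || k >= n)
    stop("in_degree must satisfy 0 < in_degree < n_neurons")
  if (!is.numeric(rewire_prob) || rewire_prob < 0 || rewire_prob > 1)
    stop("rewire_prob must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  kc <- as.integer(ceiling(k / 2))      # clockwise predecessors
  ka <- k - kc                          # counter-clockwise predecessors
  off <- c(seq_len(kc), if (ka > 0L) -seq_len(ka))
  tgt <- rep.int(seq_len(n), rep.int(k, n))
  src <- ((tgt - 1L + rep.int(off, n)) %% n) + 1L

  if (rewire_prob > 0) {
    rw <- which(stats::runif(length(src)) < rewire_prob)
    if (length(rw) > 0L) {
      # edges of target t occupy rows ((t-1)*k+1):(t*k)
      by_tgt <- split(rw, tgt[rw])
      for (tt in names(by_tgt)) {
        t_i <- as.integer(tt)
        rows <- ((t_i - 1L) * k + 1L):(t_i * k)
        cur <- src[rows]
        for (e in by_tgt[[tt]]) {
          pos <- e - (t_i - 1L) * k
          repeat {
            cand <- sample.int(n, 1L)
            if (cand != t_i && !(cand %in% cur[-pos])) break
          }
          cur[pos] <- cand
        }
        src[rows] <- cur
      }
    }
  }

  structure(
    list(n_neurons = n, in_degree = k, rewire_prob = rewire_prob,
         src = src, tgt = tgt, seed = seed),
    class = "cm_topology")
}

#' @export
print.cm_topology <- function(x, ...) {
  cat("Directed small-world topology\n")
  cat(sprintf("  N = %d neurons, in-degree k = %d, rewire prob = %g\n",
              x$n_neurons, x$in_degree, x$rewire_prob))
  cat(sprintf("  %d edges\n", length(x$src)))
  invisible(x)
}

#' Random memory patterns and external-input subset
#'
#' Draws `p` native memory patterns and one new pattern, each entry
#' independently +1 or -1 with probability 1/2, plus a subset `N'` of
#' `input_size` neurons (sampled uniformly without replacement) that will
#' carry the external input representing the new configuration.
#'
#' @param n_neurons number of neurons.
#' @param p number of native memories (>= 1).
#' @param input_size size of the external-input subset `N'` (0 disables
#'   input).
#' @param seed optional integer seed.
#' @return an object of class `cm_patterns`: list with `native` (an
#'   `n_neurons x p` matrix of +/-1), `new` (vector of +/-1), `input_set`
#'   (integer indices), `n_neurons`, `p`.
#' @export
make_patterns <- function(n_neurons, p, input_size, seed = NULL) {
  n <- as.integer(n_neurons)
  p <- as.integer(p)
  input_size <- as.integer(input_size)
  if (p < 1L) stop("p must be >= 1")
  if (input_size < 0L || input_size > n)
    stop("input_size must be between 0 and n_neurons")
  if (!is.null(seed)) set.seed(seed)
  native <- matrix(sample(c(-1, 1), n * p, replace = TRUE), nrow = n, ncol = p)
  new <- sample(c(-1, 1), n, replace = TRUE)
  input_set <- if (input_size > 0L) sort(sample.int(n, input_size)) else integer(0)
  structure(
    list(native = native, new = new, input_set = input_set,
         n_neurons = n, p = p),
    class = "cm_patterns")
}

#' @export
print.cm_patterns <- function(x, ...) {
  cat(sprintf("Pattern set: p = %d native memories on N = %d neurons; |N'| = %d\n",
              x$p, x$n_neurons, length(x$input_set)))
  invisible(x)
}

#' Memory loading of a pattern set on a given topology
#'
#' The loading `alpha = p / k` (stored patterns per unit of incoming
#' connectivity); recall fails above a maximal loading proportional to the
#' nodal degree.
#'
#' @param patterns a [make_patterns()] object.
#' @param in_degree incoming degree of the host topology (scalar).
#' @return numeric loading value.
#' @export
memory_loading <- function(patterns, in_degree) {
  patterns$p / in_degree
}

#' Embed native memories into the coupling matrix
#'
#' For every directed edge `j -> i` of the topology sets the outer-product
#' (Hebbian) coupling `J_ij = (1/p) * sum_mu xi_i,mu * xi_j,mu`; non-edges
#' carry no weight and there are no self-couplings.
#'
#' @param topology a [build_small_world()] object.
#' @param patterns a [make_patterns()] object with matching `n_neurons`.
#' @return an object of class `cm_network`: list holding the sparse coupling
#'   matrix `J` (`N x N`, `J[i, j]` = weight of edge `j -> i`), the in-degree
#'   `k`, cached edge index vectors (`edge_tgt`, `edge_src`, aligned with the
#'   internal storage order of `J`), the input bookkeeping (`input_set`,
#'   `input_weight`), and `p`.
#' @export
embed_native <- function(topology, patterns) {
  stopifnot(inherits(topology, "cm_topology"), inherits(patterns, "cm_patterns"))
  n <- topology$n_neurons
  if (patterns$n_neurons != n)
    stop("pattern length does not match the number of neurons in the topology")
  J <- Matrix::sparseMatrix(i = topology$tgt, j = topology$src, x = 1,
                            dims = c(n, n))
  # recover the edge list in J's internal (column-major) storage order
  edge_tgt <- J@i + 1L
  edge_src <- rep.int(seq_len(n), diff(J@p))
  w <- rowSums(patterns$native[edge_tgt, , drop = FALSE] *
               patterns$native[edge_src, , drop = FALSE]) / patterns$p
  J@x <- w
  structure(
    list(J = J, n_neurons = n, k = topology$in_degree,
         edge_tgt = edge_tgt, edge_src = edge_src,
         input_set = integer(0), input_weight = NA_real_,
         p = patterns$p, rewire_prob = topology$rewire_prob,
         plastic = rep(TRUE, length(edge_tgt))),
    class = "cm_network")
}

#' @export
print.cm_network <- function(x, ...) {
  cat("Coupled attractor network\n")
  cat(sprintf("  N = %d, k = %d, p = %d memories, %d weighted edges\n",
              x$n_neurons, x$k, x$p, length(x$edge_tgt)))
  if (length(x$input_set) > 0L)
    cat(sprintf("  external input wired on |N'| = %d neurons (w_e = %g)\n",
                length(x$input_set), x$input_weight))
  invisible(x)
}

#' Wire the external-input neurons into the coupling matrix
#'
#' Overwrites every *existing* edge whose source lies in the input subset
#' `N'` with the new-configuration coupling `J_ij = (w_e / p) * xi^e_i *
#' xi^e_j`. No edges are created or removed; all other weights are untouched.
#' The input returned is a new network object, the original is preserved.
#'
#' @param network a [embed_native()] network.
#' @param patterns the pattern set holding the new configuration `xi^e` and
#'   the input subset.
#' @param input_weight relative strength `w_e > 0` of the input couplings.
#' @return a new `cm_network` with the input wired; `plastic` marks the edges
#'   eligible for Hebbian updates (those not targeting a fixed neuron).
#' @export
wire_input <- function(network, patterns, input_weight) {
  stopifnot(inherits(network, "cm_network"), inherits(patterns, "cm_patterns"))
  if (length(patterns$input_set) == 0L) {
    warning("empty input set: wire_input is a no-op")
    return(network)
  }
  if (!is.numeric(input_weight) || input_weight <= 0)
    stop("input_weight must be > 0")
  xi <- patterns$new
  in_input <- logical(network$n_neurons)
  in_input[patterns$input_set] <- TRUE
  sel <- in_input[network$edge_src]
  net <- network
  net$J@x[sel] <- (input_weight / network$p) *
    xi[network$edge_tgt[sel]] * xi[network$edge_src[sel]]
  net$input_set <- patterns$input_set
  net$input_weight <- input_weight
  # edges targeting fixed neurons are never updated by plasticity: those
  # neurons are clamped and receive no relevant input
  net$plastic <- !in_input[network$edge_tgt]
  net
}

#' Export a coupling matrix as a sparse triplet file with a JSON sidecar
#'
#' Writes tab-separated `source  target  weight` triplets (0-based indices)
#' plus `<file>.json` holding the network parameters. A `.gz` extension
#' triggers gzip compression.
#'
#' @param network a `cm_network`.
#' @param file output path for the triplet table.
#' @return `file`, invisibly.
#' @export
write_coupling <- function(network, file) {
  stopifnot(inherits(network, "cm_network"))
  df <- data.frame(source = network$edge_src - 1L,
                   target = network$edge_tgt - 1L,
                   weight = network$J@x)
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  meta <- list(n_neurons = network$n_neurons, in_degree = network$k,
               p = network$p, rewire_prob = network$rewire_prob,
               input_set = network$input_set - 1L,
               input_weight = network$input_weight)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' Read a coupling matrix written by [write_coupling()]
#'
#' @param file triplet file path (the `<file>.json` sidecar must sit next to
#'   it).
#' @return a `cm_network`.
#' @export
read_coupling <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  n <- as.integer(meta$n_neurons)
  # build the structure first, then fill weights, so that structurally
  # present zero weights survive the round trip
  J <- Matrix::sparseMatrix(i = df$target + 1L, j = df$source + 1L, x = 1,
                            dims = c(n, n))
  edge_tgt <- J@i + 1L
  edge_src <- rep.int(seq_len(n), diff(J@p))
  key_internal <- (edge_src - 1) * n + edge_tgt
  key_file <- df$source * n + df$target + 1L
  J@x <- as.numeric(df$weight)[match(key_internal, key_file)]
  input_set <- as.integer(unlist(meta$input_set)) + 1L
  in_input <- logical(n)
  in_input[input_set] <- TRUE
  structure(
    list(J = J, n_neurons = n, k = as.integer(meta$in_degree),
         edge_tgt = edge_tgt, edge_src = edge_src,
         input_set = input_set,
         input_weight = if (is.null(meta$input_weight)) NA_real_ else
           as.numeric(meta$input_weight),
         p = as.integer(meta$p), rewire_prob = meta$rewire_prob,
         plastic = !in_input[edge_tgt]),
    class = "cm_network")
}
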