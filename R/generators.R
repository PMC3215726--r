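#' Girvan-Newman planted-partition benchmark
#'
#' The classical four-community benchmark: `communities` groups of `size`
#' nodes each; every unordered pair is linked independently with probability
#' `p_in = z_in / (size - 1)` inside a community and
#' `p_out = z_out / ((communities - 1) * size)` across, where
#' `z_in = total_degree - z_out`, so each node has `total_degree` links on
#' average (16 in the standard construction) of which `z_out` reach other
#' communities. Structure is clear for small `z_out` and fuzzy as `z_out`
#' grows. Being statistically homogeneous, the benchmark has no nodes that
#' are genuinely important to community structure — a null case for the
#' importance index.
#'
#' @param z_out Mean number of inter-community links per node.
#' @param seed Integer RNG seed (mandatory: realizations are reproducible).
#' @param communities,size,total_degree Benchmark shape; defaults 4, 32, 16.
#' @return A [key_graph] of `communities * size` nodes with the planted
#'   assignment in `meta$community` and the generator parameters in
#'   `meta$params`.
#' @export
generate_gn <- function(z_out, seed, communities = 4L, size = 32L,
                        total_degree = 16) {
  if (z_out < 0 || z_out > total_degree) {
    stop("keynodes usage error: need 0 <= z_out <= total_degree", call. = FALSE)
  }
  z_in <- total_degree - z_out
  p_in <- z_in / (size - 1)
  p_out <- z_out / ((communities - 1) * size)
  if (p_in > 1 || p_out > 1) {
    stop("keynodes usage error: edge probability above 1; reduce degrees",
         call. = FALSE)
  }
  n <- communities * size
  membership <- rep(seq_len(communities), each = size)
  set.seed(as.integer(seed))
  W <- matrix(0, n, n)
  same <- outer(membership, membership, `==`)
  P <- ifelse(same, p_in, p_out)
  up <- upper.tri(P)
  draw <- stats::runif(sum(up)) < P[up]
  W[up][draw] <- 1
  W <- W + t(W)
  key_graph(W, weighted = FALSE,
            meta = list(community = membership,
                        params = list(kind = "gn", z_out = z_out, z_in = z_in,
                                      communities = communities, size = size,
                                      total_degree = total_degree, seed = seed)))
}

#' Pair of disconnected Erdos-Renyi communities
#'
#' Two internally random, mutually disconnected communities of sizes
#' `n_small` and `round(q * n_small)`, each an ER graph with edge probability
#' `p`. Used to study the small-community limitation of adjacency-spectrum
#' importance: when the size ratio `q` is large, the leading eigenvalues all
#' belong to the large community and the small community's nodes become
#' invisible to the index.
#'
#' @param q Size ratio (>= 1) of the large to the small community.
#' @param p Within-community edge probability.
#' @param seed Integer RNG seed.
#' @param n_small Size of the small community (default 10).
#' @param require_connected If `TRUE`, redraw (deterministically from the
#'   seed) until both communities are internally connected; by default
#'   internally disconnected realizations are returned as drawn.
#' @return A [key_graph] with planted blocks in `meta$community`.
#' @export
generate_er_pair <- function(q, p, seed, n_small = 10L, require_connected = FALSE) {
  if (q < 1) stop("keynodes usage error: q must be >= 1", call. = FALSE)
  if (p < 0 || p > 1) stop("keynodes usage error: p must be in [0,1]", call. = FALSE)
  n_big <- as.integer(round(q * n_small))
  if (n_big < 2) stop("keynodes usage error: round(q * n_small) must be >= 2",
                      call. = FALSE)
  n <- n_small + n_big
  membership <- rep(1:2, c(n_small, n_big))
  set.seed(as.integer(seed))
  for (attempt in 1:1000) {
    W <- matrix(0, n, n)
    same <- outer(membership, membership, `==`)
    up <- upper.tri(W) & same
    W[up] <- as.numeric(stats::runif(sum(up)) < p)
    W <- W + t(W)
    g <- key_graph(W, weighted = FALSE,
                   meta = list(community = membership,
                               params = list(kind = "er_pair", q = q, p = p,
                                             n_small = n_small, seed = seed)))
    if (!require_connected) return(g)
    comp <- graph_components(g)
    if (length(unique(comp[membership == 1])) == 1 &&
        length(unique(comp[membership == 2])) == 1) return(g)
  }
  stop("keynodes computational error: could not draw internally connected ",
       "communities in 1000 attempts; lower q or raise p", call. = FALSE)
}

#' The 11-node weighted toy network
#'
#' Deterministic worked example: nodes 1-10 form a complete graph split into
#' two five-node communities \{1..5\} and \{6..10\} with designated cores 4
#' and 9. A core's links inside its community have weight 2 and its links to
#' the other community weight 0.2; all other intra-community links weigh 1
#' and all other inter-community links 0.2. Node 11 is the bridge, linked to
#' all ten nodes with weight 1. With `c = 2` the importance index singles out
#' the two cores and the bridgeness score singles out node 11.
#'
#' @return A weighted [key_graph] with `N = 11`, `m = 55`, planted roles in
#'   `meta$role`.
#' @export
generate_weighted_toy <- function() {
  W <- matrix(0, 11, 11)
  comm <- c(rep(1, 5), rep(2, 5))
  cores <- c(4, 9)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      W[i, j] <- if (comm[i] == comm[j]) {
        if (i %in% cores || j %in% cores) 2 else 1
      } else {
        0.2
      }
    }
  }
  W[1:10, 11] <- 1
  W <- W + t(W) - diag(diag(W))
  role <- c(rep("peripheral", 10), "bridge")
  role[cores] <- "core"
  key_graph(W, weighted = TRUE,
            meta = list(community = c(comm, NA), role = role,
                        params = list(kind = "weighted_toy")))
}

#' Random two-community sketch with planted cores and a bridge
#'
#' Fixture emulating the canonical 15-node two-community sketch: two
#' communities of `community_size` nodes, each with one hub (the planted
#' core) adjacent to every other member, the non-hub members forming a
#' sparse ring, plus one bridge node adjacent to three random non-hub
#' members of each community. With the default size 7 the graph has
#' `2 * 7 + 1 = 15` nodes. The planted hubs attain the top importance and
#' the bridge the minimum bridgeness score.
#'
#' @param community_size Nodes per community (>= 3), default 7.
#' @param seed Integer RNG seed (the bridge attachments are random).
#' @return A [key_graph] with planted roles in `meta$role`.
#' @export
generate_core_bridge_sketch <- function(community_size = 7L, seed) {
  s <- as.integer(community_size)
  if (s < 3) stop("keynodes usage error: community_size must be >= 3", call. = FALSE)
  set.seed(as.integer(seed))
  n <- 2L * s + 1L
  W <- matrix(0, n, n)
  for (base in c(0L, s)) {
    hub <- base + 1L
    members <- (base + 2L):(base + s)
    W[hub, members] <- 1
    nm <- length(members)
    if (nm > 1) {
      for (idx in seq_len(nm)) {
        u <- members[idx]; v <- members[if (idx == nm) 1 else idx + 1]
        W[u, v] <- 1; W[v, u] <- 1
      }
    }
  }
  bridge <- n
  k_attach <- min(3L, s - 1L)
  for (base in c(0L, s)) {
    members <- (base + 2L):(base + s)
    att <- if (length(members) <= k_attach) members else sample(members, k_attach)
    W[bridge, att] <- 1
  }
  W <- pmax(W, t(W))
  role <- rep("peripheral", n)
  role[c(1L, s + 1L)] <- "core"
  role[bridge] <- "bridge"
  key_graph(W, weighted = FALSE,
            meta = list(community = c(rep(1L, s), rep(2L, s), NA),
                        role = role,
                        params = list(kind = "core_bridge_sketch",
                                      community_size = s, seed = seed)))
}

#' LFR-style benchmark via the networkx generator
#'
#' Adapter around the established LFR implementation in Python networkx
#' (`LFR_benchmark_graph`): power-law degree and community-size
#' distributions, community structure controlled by the mixing parameter
#' `mu`. The harness accepts any graph with planted labels; this function is
#' the bundled way to obtain one. Generation retries deterministically over
#' seeds derived from `seed` because the LFR construction does not converge
#' for every seed.
#'
#' @param n Number of nodes (default 1000).
#' @param mu Mixing parameter: the fraction of each node's links that leave
#'   its community (default 0.1, a clear structure).
#' @param seed Integer RNG seed.
#' @param tau1,tau2 Degree and community-size power-law exponents (3, 1.5).
#' @param average_degree,min_community Remaining LFR shape parameters
#'   (15, 20).
#' @param python Python interpreter to invoke (default `"python"` on the
#'   PATH; must have networkx available).
#' @param max_attempts Seeds to try before giving up (default 12).
#' @return A [key_graph] with the planted assignment in `meta$community`.
#' @export
generate_lfr <- function(n = 1000L, mu = 0.1, seed, tau1 = 3, tau2 = 1.5,
                         average_degree = 15, min_community = 20L,
                         python = "python", max_attempts = 12L) {
  dir <- tempfile("lfr")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  edge_file <- file.path(dir, "edges.tsv")
  comm_file <- file.path(dir, "communities.tsv")
  script <- file.path(dir, "lfr.py")
  writeLines(c(
    "import sys, networkx as nx",
    "n, tau1, tau2, mu, avg, minc = int(sys.argv[1]), float(sys.argv[2]), float(sys.argv[3]), float(sys.argv[4]), float(sys.argv[5]), int(sys.argv[6])",
    "seeds = [int(s) for s in sys.argv[7].split(',')]",
    "edge_out, comm_out = sys.argv[8], sys.argv[9]",
    "G = None",
    "for s in seeds:",
    "    try:",
    "        G = nx.LFR_benchmark_graph(n, tau1, tau2, mu, average_degree=avg,",
    "                                   min_community=minc, seed=s, max_iters=500)",
    "        break",
    "    except Exception:",
    "        continue",
    "if G is None:",
    "    sys.exit(3)",
    "comms = {}",
    "for v in G:",
    "    key = frozenset(G.nodes[v]['community'])",
    "    comms.setdefault(key, len(comms) + 1)",
    "with open(edge_out, 'w') as fh:",
    "    for u, v in G.edges():",
    "        if u != v:",
    "            fh.write(f'{u + 1} {v + 1}\\n')",
    "with open(comm_out, 'w') as fh:",
    "    for v in sorted(G):",
    "        fh.write(f\"{v + 1}\\t{comms[frozenset(G.nodes[v]['community'])]}\\n\")"
  ), script)
  seeds <- (as.integer(seed) + 10007L * (seq_len(max_attempts) - 1L)) %% .Machine$integer.max
  status <- system2(python, c(script, n, tau1, tau2, mu, average_degree,
                              min_community, paste(seeds, collapse = ","),
                              edge_file, comm_file),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(edge_file)) {
    stop("keynodes computational error: LFR generation failed after ",
         max_attempts, " attempts (is networkx available to '", python, "'?)",
         call. = FALSE)
  }
  g <- load_graph(edge_file, format = "edgelist", weighted = FALSE)
  comm <- utils::read.table(comm_file, col.names = c("node", "community"))
  membership <- comm$community[match(g$labels, as.character(comm$node))]
  g$meta <- list(community = as.integer(membership),
                 params = list(kind = "lfr", n = n, mu = mu, tau1 = tau1,
                               tau2 = tau2, average_degree = average_degree,
                               min_community = min_community, seed = seed))
  g
}
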