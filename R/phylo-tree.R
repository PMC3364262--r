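#' Parse and write Newick trees
#'
#' Thin, validating wrappers around \pkg{ape}'s Newick reader/writer.
#' Parsing rejects duplicate tip labels and malformed strings; writing uses
#' 10 significant digits so a round trip preserves branch lengths.
#'
#' @param text a Newick string (or path contents) describing a rooted tree.
#' @return for `parse_newick`, an \pkg{ape} `phylo`; for `write_newick`, a
#'   Newick string.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}

# depth (distance from root) of every node, in edge-length units
.node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  depth <- numeric(n_all)
  # edges are not guaranteed preorder; process until stable
  ord <- reorder(tree, "cladewise")$edge
  len <- reorder(tree, "cladewise")$edge.length
  if (is.null(len)) len <- rep(1, nrow(ord))
  for (i in seq_len(nrow(ord))) {
    depth[ord[i, 2]] <- depth[ord[i, 1]] + len[i]
  }
  depth
}

#' Time-scale a composite tree from node and tip ages
#'
#' Assigns ages (Ma before present, 0 = extant) to every node of a rooted
#' topology from a table of dated tips and internal nodes, then sets branch
#' lengths to age differences. Undated internal nodes lying between dated
#' nodes are spaced so the intervening branches are equal (the
#' equal-sharing rule used when divergence dates are unavailable). Fossil
#' tips take their stated age; a (first, last) range is summarised by its
#' midpoint. Tips absent from `ages` are treated as extant (0 Ma).
#'
#' @param tree a rooted `phylo`; internal nodes addressed via
#'   `tree$node.label`.
#' @param ages named numeric vector of ages in Ma: names are tip labels or
#'   internal node labels. The root must be dated.
#' @return a `phylo` with branch lengths in Ma; `node.age` attribute holds
#'   all node ages.
#' @export
scale_to_dates <- function(tree, ages) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  age <- rep(NA_real_, n_all)
  age[seq_len(n_tip)] <- 0
  idx <- match(names(ages), tree$tip.label)
  age[idx[!is.na(idx)]] <- ages[!is.na(idx)]
  if (!is.null(tree$node.label)) {
    idx <- match(names(ages), tree$node.label)
    hit <- !is.na(idx)
    age[n_tip + idx[hit]] <- ages[hit]
  }
  if (is.na(age[root])) stop("the root must be dated")
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])
  dated <- !is.na(age)
  # nearest dated ancestor and step count
  nearest_dated_anc <- function(v) {
    steps <- 0L
    u <- v
    repeat {
      u <- parent[u]
      steps <- steps + 1L
      if (u == 0L) stop("node has no dated ancestor")
      if (dated[u]) return(list(node = u, steps = steps))
    }
  }
  # dated descendants reachable through undated intermediates, with step
  # counts from v
  dated_desc <- function(v) {
    out_node <- integer(0); out_steps <- integer(0)
    stack_n <- unlist(children[as.character(v)], use.names = FALSE)
    stack_s <- rep(1L, length(stack_n))
    while (length(stack_n)) {
      u <- stack_n[1L]; s <- stack_s[1L]
      stack_n <- stack_n[-1L]; stack_s <- stack_s[-1L]
      if (dated[u]) {
        out_node <- c(out_node, u); out_steps <- c(out_steps, s)
      } else {
        kids <- unlist(children[as.character(u)], use.names = FALSE)
        stack_n <- c(stack_n, kids)
        stack_s <- c(stack_s, rep(s + 1L, length(kids)))
      }
    }
    list(node = out_node, steps = out_steps)
  }
  for (v in setdiff(seq_len(n_all), which(dated))) {
    anc <- nearest_dated_anc(v)
    des <- dated_desc(v)
    t_a <- age[anc$node]
    cand <- t_a - (t_a - age[des$node]) * anc$steps / (anc$steps + des$steps)
    age[v] <- max(cand)
  }
  # consistency: every parent at least as old as its children
  bl <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(bl < -1e-8)) {
    bad <- which(bl < -1e-8)[1L]
    lab <- function(i) if (i <= n_tip) tree$tip.label[i] else paste0("node", i)
    stop("node ", lab(tree$edge[bad, 2]), " dated older (",
         age[tree$edge[bad, 2]], " Ma) than its ancestor ",
         lab(tree$edge[bad, 1]), " (", age[tree$edge[bad, 1]], " Ma)")
  }
  tree$edge.length <- pmax(bl, 0)
  attr(tree, "node.age") <- age
  tree
}

#' Branch-length transforms
#'
#' Standard arbitrary and model-based branch-length schemes used to supply
#' or adjust divergence times on composite trees:
#' \describe{
#'   \item{grafen}{node height = (descendant tip count - 1), normalized to
#'     root height 1, raised to the power `param` (rho); ignores existing
#'     lengths.}
#'   \item{pagel_equal}{every branch set to 1; ignores existing lengths.}
#'   \item{ou}{the Ornstein-Uhlenbeck depth transform with strength
#'     `param` (alpha); reduces to the identity as alpha -> 0.}
#'   \item{power}{each branch length raised to `param`; the
#'     Brownian-motion conformance step applied before simulation-null
#'     tests when model comparison rejects BM on the raw tree.}
#' }
#'
#' @param tree a `phylo` (with branch lengths except for
#'   `grafen`/`pagel_equal`).
#' @param mode one of `"grafen"`, `"pagel_equal"`, `"ou"`, `"power"`.
#' @param param transform parameter (rho, alpha or the exponent); must be
#'   positive for `ou` and `power`.
#' @return a `phylo` with transformed branch lengths.
#' @export
transform_branches <- function(tree,
                               mode = c("grafen", "pagel_equal", "ou",
                                        "power"),
                               param = 1) {
  mode <- match.arg(mode)
  n_tip <- length(tree$tip.label)
  if (mode %in% c("ou", "power") && param <= 0) {
    stop("param must be positive for mode '", mode, "'")
  }
  if (mode == "pagel_equal") {
    tree$edge.length <- rep(1, nrow(tree$edge))
    return(tree)
  }
  if (mode == "grafen") {
    n_desc <- .n_descendant_tips(tree)
    h <- pmax(n_desc - 1, 0) / (n_tip - 1)
    h <- h^param
    tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
    return(tree)
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  depth <- .node_depths(tree)
  t1 <- depth[tree$edge[, 1]]
  t2 <- depth[tree$edge[, 2]]
  if (mode == "ou") {
    a <- param
    T_max <- max(depth[seq_len(n_tip)])
    tree$edge.length <-
      (1 / (2 * a)) * exp(-2 * a * (T_max - t2)) * (1 - exp(-2 * a * (t2 - t1)))
  } else { # power
    tree$edge.length <- tree$edge.length^param
  }
  tree
}

.n_descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  cnt <- c(rep(1L, n_tip), rep(0L, tree$Nnode))
  ord <- reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(ord))) {
    cnt[ord[i, 1]] <- cnt[ord[i, 1]] + cnt[ord[i, 2]]
  }
  cnt
}

#' Phylogenetic covariance with Pagel's lambda scaling
#'
#' Builds the tips x tips matrix of shared root-to-tip path lengths and
#' multiplies the off-diagonal entries by `lambda` in [0, 1]: 0 removes all
#' phylogenetic covariance (star structure), 1 is full Brownian-motion
#' covariance. Zero-length branches are floored at 1e-8 Ma first (logged),
#' so the matrix is invertible.
#'
#' @param tree a `phylo` with branch lengths.
#' @param lambda scaling of off-diagonal covariance, in [0, 1].
#' @return a `phylo_covariance`: list with `labels`, `V` (symmetric PSD),
#'   `lambda`.
#' @export
vcv_with_lambda <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 1e-8)) {
    message("vcv_with_lambda: flooring ",
            sum(tree$edge.length < 1e-8), " zero-length branch(es) at 1e-8")
    tree$edge.length <- pmax(tree$edge.length, 1e-8)
  }
  V <- ape::vcv.phylo(tree)
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  structure(list(labels = tree$tip.label, V = V, lambda = lambda),
            class = "phylo_covariance")
}

#' Simulate Brownian-motion traits on a tree
#'
#' Draws tip values from the multivariate normal with mean `root_value` and
#' covariance `sigma2 * V`, where V is the shared path-length matrix of the
#' tree. Deterministic for a given seed.
#'
#' @param tree a `phylo` with branch lengths.
#' @param sigma2 Brownian rate (variance per Ma), >= 0.
#' @param root_value trait value at the root.
#' @param n_traits number of independent traits to simulate.
#' @param seed RNG seed (required).
#' @return tips x traits numeric matrix with tip labels as rownames.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, n_traits = 1L,
                        seed) {
  if (missing(seed)) stop("seed is required")
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  set.seed(seed)
  n <- length(tree$tip.label)
  X <- matrix(root_value, n, n_traits,
              dimnames = list(tree$tip.label,
                              paste0("trait", seq_len(n_traits))))
  if (sigma2 > 0) {
    V <- vcv_with_lambda(tree, 1)$V
    L <- t(.chol_safe(V))
    Z <- matrix(stats::rnorm(n * n_traits), n, n_traits)
    X <- X + sqrt(sigma2) * (L %*% Z)
  }
  X
}

#' Select the Brownian-conformance power exponent
#'
#' Searches a grid of exponents for the power branch-length transform and
#' returns the one maximizing the Brownian-motion log-likelihood of the
#' focal trait on the transformed tree (the criterion used before
#' simulation-null tests when the raw tree departs from BM).
#'
#' @param trait named numeric vector by tip.
#' @param tree a `phylo` with branch lengths.
#' @param grid candidate exponents (default `seq(0.1, 3, by = 0.05)`).
#' @return list with `exponent`, `logL`, and the transformed `tree`.
#' @export
power_conformance <- function(trait, tree, grid = seq(0.1, 3, by = 0.05)) {
  .stopifnot_tips(trait, tree)
  x <- .match_tips(trait, tree)
  ll <- vapply(grid, function(p) {
    tr <- transform_branches(tree, "power", p)
    V <- vcv_with_lambda(tr, 1)$V
    .bm_loglik(x, V)
  }, numeric(1))
  best <- which.max(ll)
  list(exponent = grid[best], logL = ll[best],
       tree = transform_branches(tree, "power", grid[best]))
}

# profile BM log-likelihood of x under correlation structure C (sigma2 and
# the root profiled out analytically)
.bm_loglik <- function(x, C) {
  n <- length(x)
  R <- .chol_safe(C)
  a <- .gls_root(R, x)
  r <- x - a
  q <- sum(.chol_solve(R, r) * r)
  s2 <- q / n
  -0.5 * (n * log(2 * pi) + n * log(s2) + .logdet_chol(R) + n)
}
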