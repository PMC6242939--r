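#' Configuration for the bifurcating-trajectory generator
#'
#' Emulates a developmental trajectory that bifurcates into two fate
#' arms, with one cluster placed at the branch point and simulated as an
#' unstable transition state: its cells receive `noise_inflation`-fold
#' inflated count noise and their loading on the shared coordination
#' program is scaled by `coordination_drop`, reproducing the elevated
#' cell-to-cell variability and reduced gene-to-gene coordination that
#' characterize transition states.
#'
#' Cells are laid out in five pseudotime bins: two pre-branch clusters,
#' the transition cluster centered on `branch_point`, and one
#' post-branch cluster per arm.
#'
#' @param n_genes,n_cells dimensions (defaults 1000 genes, 300 cells).
#' @param branch_point pseudotime of the bifurcation, in (0, 1).
#' @param transition_cluster id (1-5) of the cluster treated as the
#'   transition state; default 3, the bin straddling the branch point.
#' @param noise_inflation dispersion multiplier in the transition
#'   cluster (>= 1).
#' @param coordination_drop factor in (0, 1] scaling the shared-program
#'   loading of transition cells.
#' @param seed RNG seed.
#' @return A list of class `sct_traj_sim_config`.
#' @export
trajectory_sim_config <- function(n_genes = 1000, n_cells = 300,
                                  branch_point = 0.5, transition_cluster = 3,
                                  noise_inflation = 3, coordination_drop = 0.5,
                                  seed = 1) {
  check_count(n_genes, "n_genes", 20)
  check_count(n_cells, "n_cells", 25)
  check_fraction(branch_point, "branch_point")
  check_count(transition_cluster, "transition_cluster", 1)
  if (transition_cluster > 5)
    stop("configuration error: `transition_cluster` must be in 1..5")
  if (noise_inflation < 1)
    stop("configuration error: `noise_inflation` must be >= 1")
  if (coordination_drop <= 0 || coordination_drop > 1)
    stop("configuration error: `coordination_drop` must lie in (0,1]")
  structure(list(n_genes = n_genes, n_cells = n_cells,
                 branch_point = branch_point,
                 transition_cluster = transition_cluster,
                 noise_inflation = noise_inflation,
                 coordination_drop = coordination_drop, seed = seed),
            class = "sct_traj_sim_config")
}

#' Simulate a bifurcating trajectory with a transition state
#'
#' Genes follow sigmoidal programs of ground-truth pseudotime; the two
#' post-branch arms share all pre-branch programs and diverge through
#' arm-specific programs active only after `branch_point`. A shared
#' latent factor couples a module of genes within every cell
#' (gene-to-gene coordination); transition-cluster cells have this
#' coupling attenuated by `coordination_drop` and their negative-binomial
#' dispersion inflated by `noise_inflation`.
#'
#' @param config an [trajectory_sim_config()].
#' @return List with `counts` (an [count_matrix()]) and `truth`:
#'   `cell_cluster` (1-5), `cell_pseudotime`, `cell_arm` ("A"/"B" after
#'   the branch, NA before), `transition_cluster`, `flanking_clusters`,
#'   `dynamic_genes` (sigmoid program genes), `monotone_genes` (strictly
#'   monotone strong programs), `module_genes` (shared-coordination
#'   module), `arm_genes` per arm.
#' @export
generate_trajectory_counts <- function(config = trajectory_sim_config()) {
  stopifnot(inherits(config, "sct_traj_sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes; N <- config$n_cells
    bp <- config$branch_point
    gene_ids <- sprintf("gene_%04d", seq_len(G))
    # five pseudotime bins: pre-branch (2), transition around bp, two arms
    half_w <- 0.05
    breaks <- c(0, bp * 0.55, bp - half_w, bp + half_w, 1)
    cluster <- sort(rep_len(1:5, N))
    t <- numeric(N)
    t[cluster == 1] <- runif(sum(cluster == 1), breaks[1], breaks[2])
    t[cluster == 2] <- runif(sum(cluster == 2), breaks[2], breaks[3])
    t[cluster == 3] <- runif(sum(cluster == 3), breaks[3], breaks[4])
    t[cluster == 4] <- runif(sum(cluster == 4), breaks[4], breaks[5])
    t[cluster == 5] <- runif(sum(cluster == 5), breaks[4], breaks[5])
    arm <- ifelse(cluster == 4, "A", ifelse(cluster == 5, "B", NA))

    n_dyn <- round(0.3 * G)      # genes with pseudotime programs
    n_arm <- round(0.1 * G)      # arm-specific programs per arm
    n_mod <- round(0.3 * G)      # shared-coordination module
    n_mono <- min(20L, n_dyn)    # strong strictly monotone programs
    dyn <- sample.int(G, n_dyn)
    armA <- sample(setdiff(seq_len(G), dyn), n_arm)
    armB <- sample(setdiff(seq_len(G), c(dyn, armA)), n_arm)
    mono <- dyn[seq_len(n_mono)]
    # the coordination module sits on the dynamic program genes: those are
    # the genes whose mutual coupling a transition state loses. The strong
    # monotone reporters are kept out so they track pseudotime cleanly.
    module <- setdiff(dyn, mono)

    base_log2 <- rnorm(G, mean = 2, sd = 1.5)
    base_log2[mono] <- pmax(base_log2[mono], 4)  # reporters need signal over shot noise
    logmu <- matrix(base_log2, G, N)
    # shared sigmoidal programs of pseudotime
    center <- runif(n_dyn, 0.1, 0.9)
    slope <- runif(n_dyn, 0.05, 0.15)
    amp <- sample(c(-1, 1), n_dyn, TRUE) * runif(n_dyn, 1.5, 3)
    amp[seq_len(n_mono)] <- sample(c(-1, 1), n_mono, TRUE) * 6
    for (j in seq_len(n_dyn)) {
      logmu[dyn[j], ] <- logmu[dyn[j], ] + if (j <= n_mono)
        amp[j] * t  # linear reporters track pseudotime over the full range
      else
        amp[j] / (1 + exp(-(t - center[j]) / slope[j]))
    }
    # arm-specific programs, active only past the branch point
    for (set in list(list(idx = armA, arm = "A"), list(idx = armB, arm = "B"))) {
      cA <- runif(length(set$idx), bp, 0.95)
      sA <- runif(length(set$idx), 0.05, 0.12)
      aA <- runif(length(set$idx), 2, 3.5)
      on <- !is.na(arm) & arm == set$arm
      for (j in seq_along(set$idx))
        logmu[set$idx[j], on] <- logmu[set$idx[j], on] +
          aA[j] / (1 + exp(-(t[on] - cA[j]) / sA[j]))
    }
    # shared latent coordination factor, attenuated in the transition state
    u <- rnorm(N)
    loading <- numeric(G)
    loading[module] <- rnorm(length(module), 0, 0.6)
    lambda <- ifelse(cluster == config$transition_cluster,
                     config$coordination_drop, 1)
    logmu <- logmu + outer(loading, u * lambda)

    mu <- 2^logmu
    disp <- rep(0.15, N)
    disp[cluster == config$transition_cluster] <-
      0.15 * config$noise_inflation
    counts <- matrix(rnbinom(G * N, mu = as.numeric(mu),
                             size = rep(1 / disp, each = G)), G, N)
    cm <- count_matrix(counts, feature_ids = gene_ids,
                       cell_ids = sprintf("cell_%04d", seq_len(N)),
                       cell_meta = data.frame(cluster = cluster,
                                              pseudotime = t, arm = arm))
    tc <- config$transition_cluster
    flank <- intersect(c(tc - 1L, tc + 1L, if (tc == 3L) 5L), 1:5)
    flank <- setdiff(flank, tc)
    list(counts = cm,
         truth = list(cell_cluster = cluster, cell_pseudotime = t,
                      cell_arm = arm,
                      transition_cluster = config$transition_cluster,
                      flanking_clusters = flank,
                      dynamic_genes = gene_ids[dyn],
                      monotone_genes = gene_ids[mono],
                      module_genes = gene_ids[module],
                      arm_genes = list(A = gene_ids[armA], B = gene_ids[armB])))
  })
}
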