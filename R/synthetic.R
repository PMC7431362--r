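# Synthetic protein-like Calpha traces and graded-noise decoys with known
# true quality, so the whole train/score/benchmark pipeline is testable with
# no external structures.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

# Kyte-Doolittle hydropathy; hydrophobic residues are preferentially placed
# at buried positions of the trace, which is what gives the 20 residue types
# distinct pairwise distance distributions (the signal a knowledge-based
# potential extracts).
HYDROPATHY <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
                GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
                LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
                SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

# Sample one residue name per position: composition weights tilted by
# exp(beta * hydropathy * centrality), centrality in [-0.5, 0.5] from the
# rank of the position's distance to the chain centroid (0.5 = most buried).
assign_residues_by_burial <- function(xyz, composition, beta = 5) {
  n <- nrow(xyz)
  rad <- sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
  centrality <- 0.5 - (rank(rad, ties.method = "first") - 1) / (n - 1)
  h <- HYDROPATHY / 4.5
  base <- composition / sum(composition)
  vapply(centrality, function(ci) {
    w <- base * exp(beta * h * ci)
    sample(STANDARD_AA, 1, prob = w)
  }, character(1))
}

#' Generate a synthetic native Calpha trace
#'
#' Builds a protein-like single chain: consecutive Calpha atoms at 3.8
#' Angstrom virtual-bond distance, self-avoiding (no non-bonded pair below
#' 3.5 Angstrom), with residue names drawn from a composition over the 20
#' standard amino acids. Deterministic for a fixed seed.
#'
#' Fold types: `"helix"` is an ideal alpha-helix (2.3 Angstrom radius, 1.5
#' Angstrom rise, 100 degrees per residue); `"random_walk"` is an unbiased
#' self-avoiding walk; `"mixed"` (default) is a self-avoiding walk with
#' directional persistence and a pull toward its own centroid, giving
#' compact globule-like traces whose residues are then assigned by burial
#' depth: buried positions draw preferentially hydrophobic residues
#' (Kyte-Doolittle scale), surface positions polar ones. This hydrophobic
#' core organisation is what gives each residue pair type a distinct
#' distance distribution - the signal a knowledge-based potential extracts.
#'
#' @param n_residues Chain length (>= 5).
#' @param seed Integer seed.
#' @param fold_type One of `"mixed"`, `"helix"`, `"random_walk"`.
#' @param composition Probability weights over the 20 standard amino acids
#'   (default uniform).
#' @param identifier Model identifier (default derived from seed).
#' @param with_cb Also place a pseudo-CB atom 1.5 Angstrom from each
#'   non-glycine CA (exercises multi-atom typing).
#' @return A [structure_model()].
#' @export
generate_native <- function(n_residues, seed, fold_type = c("mixed", "helix",
                                                            "random_walk"),
                            composition = NULL, identifier = NULL,
                            with_cb = FALSE) {
  stopifnot(n_residues >= 5)
  fold_type <- match.arg(fold_type)
  if (is.null(composition)) composition <- rep(1, 20)
  if (is.null(identifier)) identifier <- sprintf("syn_%s_%d", fold_type, seed)
  with_seed(seed, {
    xyz <- switch(fold_type,
                  helix = helix_trace(n_residues),
                  random_walk = saw_trace(n_residues, persistence = 0,
                                          compact = 0),
                  mixed = saw_trace(n_residues, persistence = 0.6,
                                    compact = 0.35))
    res <- if (fold_type == "mixed")
      assign_residues_by_burial(xyz, composition)
    else
      sample(STANDARD_AA, n_residues, replace = TRUE,
             prob = composition / sum(composition))
    atoms <- data.frame(residue_name = res, atom_name = "CA",
                        residue_index = 0:(n_residues - 1L), chain_id = "A",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
    if (with_cb) atoms <- add_pseudo_cb(atoms, xyz)
    structure_model(identifier, atoms)
  })
}

helix_trace <- function(n) {
  t <- (0:(n - 1)) * (100 * pi / 180)
  cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (0:(n - 1)))
}

saw_trace <- function(n, persistence, compact, bond = 3.8, clash = 3.5,
                      max_tries = 60, max_backtracks = NULL) {
  if (is.null(max_backtracks)) max_backtracks <- 60L * n
  xyz <- matrix(0, n, 3)
  dir <- unit(stats::rnorm(3))
  xyz[2, ] <- bond * dir
  k <- 3L
  backtracks <- 0L
  while (k <= n) {
    placed <- FALSE
    centroid <- colMeans(xyz[1:(k - 1), , drop = FALSE])
    for (try in seq_len(max_tries)) {
      pull <- unit(centroid - xyz[k - 1, ])
      prop <- unit(persistence * dir + stats::rnorm(3) + compact * pull)
      cand <- xyz[k - 1, ] + bond * prop
      prev <- xyz[1:(k - 2), , drop = FALSE]   # non-bonded atoms only
      d2 <- rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2)
      if (all(d2 >= clash^2)) {
        xyz[k, ] <- cand
        dir <- prop
        placed <- TRUE
        break
      }
    }
    if (placed) {
      k <- k + 1L
    } else {
      # dead end: unwind a few steps and regrow from there
      backtracks <- backtracks + 1L
      if (backtracks > max_backtracks)
        stop("chain placement failed after ", max_backtracks,
             " backtracks; retry with another seed or a larger box ",
             "(lower compactness)")
      k <- max(3L, k - 5L)
      dir <- unit(xyz[k - 1, ] - xyz[k - 2, ])
    }
  }
  xyz
}

add_pseudo_cb <- function(atoms, xyz) {
  n <- nrow(xyz)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- atoms[i, , drop = FALSE]
    if (atoms$residue_name[i] != "GLY") {
      lo <- max(1, i - 1); hi <- min(n, i + 1)
      away <- unit(xyz[i, ] - colMeans(xyz[c(lo, hi), , drop = FALSE]))
      cb <- xyz[i, ] + 1.5 * away
      rows <- rbind(rows, data.frame(residue_name = atoms$residue_name[i],
                                     atom_name = "CB",
                                     residue_index = atoms$residue_index[i],
                                     chain_id = atoms$chain_id[i],
                                     x = cb[1], y = cb[2], z = cb[3],
                                     stringsAsFactors = FALSE))
    }
    out[[i]] <- rows
  }
  do.call(rbind, out)
}

#' Generate a noisy decoy of a native model
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sigma` to every
#' coordinate. Residue identities are preserved; `sigma = 0` returns an
#' exact copy. Self-avoidance is deliberately not re-imposed: the clashes
#' appearing at high noise are precisely the non-native signal a potential
#' must penalize.
#'
#' @param native A [structure_model()].
#' @param sigma Noise level in Angstrom (>= 0).
#' @param seed Integer seed.
#' @param identifier Decoy identifier (default derived from the native's).
#' @return A [structure_model()].
#' @export
generate_decoy <- function(native, sigma, seed, identifier = NULL) {
  stopifnot(sigma >= 0)
  if (is.null(identifier))
    identifier <- sprintf("%s_s%g_%d", native$identifier, sigma, seed)
  at <- native$atoms
  with_seed(seed, {
    n <- nrow(at)
    at$x <- at$x + stats::rnorm(n, 0, sigma)
    at$y <- at$y + stats::rnorm(n, 0, sigma)
    at$z <- at$z + stats::rnorm(n, 0, sigma)
    structure_model(identifier, at)
  })
}

kabsch_rotation <- function(P, Q) {
  # rotation R minimizing || P R - Q ||_F for centered P, Q (n x 3)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Simplified TM-style quality of a model against a reference
#'
#' Optimal least-squares superposition of the two Calpha sets (Kabsch
#' rotation + translation), then
#' \eqn{q = (1/L) \sum_i 1/(1 + (d_i/d_0)^2)} with
#' \eqn{d_0 = \max(1.24 (L - 15)^{1/3} - 1.8, 0.5)}. This assumes equal
#' length and a 1:1 residue correspondence; it is a simplified stand-in for
#' TM-score (no alignment search or iterative seed extension), adequate for
#' same-topology synthetic decoys only.
#'
#' @param reference,model [structure_model()] objects of equal length.
#' @return Quality in `(0, 1]`; 1 for identical (or rigidly moved) inputs.
#' @export
toy_quality <- function(reference, model) {
  P <- ca_coords(model)
  Q <- ca_coords(reference)
  if (nrow(P) != nrow(Q))
    stop("length mismatch: ", nrow(P), " vs ", nrow(Q), " residues")
  L <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  R <- kabsch_rotation(Pc, Qc)
  d <- sqrt(rowSums((Pc %*% R - Qc)^2))
  x <- L - 15
  d0 <- max(1.24 * sign(x) * abs(x)^(1 / 3) - 1.8, 0.5)
  mean(1 / (1 + (d / d0)^2))
}

ca_coords <- function(model) {
  at <- model$atoms[model$atoms$atom_name == "CA", , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Generate a full toy decoy benchmark set
#'
#' For each target, one native plus `decoys_per_target` graded-noise decoys
#' (noise levels cycled over `sigmas`) with toy-quality labels, mimicking
#' the layout of decoy benchmark datasets. Deterministic per seed.
#'
#' @param n_targets Number of targets.
#' @param decoys_per_target Decoys per target.
#' @param sigmas Noise levels in Angstrom, cycled over the decoys so that
#'   qualities span the near-native to poor range. Defaults span 0.5-12.
#' @param seed Integer seed.
#' @param n_residues Length range (inclusive) from which each target's chain
#'   length is drawn; default 80-250 residues.
#' @param fold_type Fold type passed to [generate_native()].
#' @return List with `models` (named list of [structure_model()], natives
#'   included) and `quality` (data.frame target/model/metric/value/sigma;
#'   natives have sigma 0 and quality 1).
#' @export
generate_benchmark_set <- function(n_targets, decoys_per_target,
                                   sigmas = c(0.5, 1, 2, 3, 5, 8, 12),
                                   seed = 1, n_residues = c(80L, 250L),
                                   fold_type = "mixed") {
  stopifnot(n_targets >= 1, decoys_per_target >= 1, all(sigmas >= 0))
  models <- list()
  qual <- vector("list", n_targets)
  lens <- with_seed(seed, sample(seq(n_residues[1], n_residues[2]),
                                 n_targets, replace = TRUE))
  for (t in seq_len(n_targets)) {
    tid <- sprintf("t%03d", t)
    tseed <- (seed * 10007L + t * 101L) %% .Machine$integer.max
    native <- generate_native(lens[t], seed = tseed, fold_type = fold_type,
                              identifier = paste0(tid, "_native"))
    models[[native$identifier]] <- native
    sg <- rep_len(sigmas, decoys_per_target)
    rows <- data.frame(target = tid, model = native$identifier,
                       metric = "toy_quality", value = 1, sigma = 0,
                       stringsAsFactors = FALSE)
    for (k in seq_len(decoys_per_target)) {
      dec <- generate_decoy(native, sg[k], seed = tseed + k,
                            identifier = sprintf("%s_d%03d", tid, k))
      models[[dec$identifier]] <- dec
      rows <- rbind(rows, data.frame(target = tid, model = dec$identifier,
                                     metric = "toy_quality",
                                     value = toy_quality(native, dec),
                                     sigma = sg[k], stringsAsFactors = FALSE))
    }
    qual[[t]] <- rows
  }
  list(models = models, quality = do.call(rbind, qual))
}

#' Write a structure model as a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$residue_index + 1L,
                   resid = at$residue_name,
                   elety = at$atom_name,
                   chain = at$chain_id)
  invisible(path)
}
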