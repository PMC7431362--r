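# Shared fixtures and independent oracles for the test suite.

# Minimal PDB writer for hand-built fixtures (fixed-width ATOM records).
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", record = "ATOM", element = "") {
  if (nchar(element) == 0)
    element <- substr(trimws(name), 1, 1)
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, alt, resname, chain, resno, x, y, z,
          occ, 0, element)
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a 3-residue Calpha-only chain (ALA-GLY-CYS) on a line, 3.8 A spacing
three_res_pdb <- function() {
  write_fixture_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0.0, 0.0),
    pdb_atom_line(3, "CA", "CYS", "A", 3, 7.6, 0.0, 0.0)
  ))
}

# collinear Calpha chain of n residues with given spacing
collinear_model <- function(n, spacing = 3.8, resname = "ALA") {
  structure_model("line", data.frame(
    residue_name = resname, atom_name = "CA",
    residue_index = 0:(n - 1), chain_id = "A",
    x = spacing * (0:(n - 1)), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

# O(n^2) double-loop oracle for qualifying pair enumeration
brute_force_pairs <- function(model, min_separation = 4, cutoff = 15) {
  at <- model$atoms
  n <- nrow(at)
  keys <- character(0); dists <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(at$residue_index[i] - at$residue_index[j]) < min_separation)
          next
        d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                    (at$z[i] - at$z[j])^2)
        if (d >= cutoff) next
        keys <- c(keys, pair_type_key(
          paste0(at$residue_name[i], ":", at$atom_name[i]),
          paste0(at$residue_name[j], ":", at$atom_name[j])))
        dists <- c(dists, d)
      }
    }
  }
  data.frame(key = keys, distance = dists, stringsAsFactors = FALSE)
}

# double-loop oracle for whole-model scoring
brute_force_score <- function(model, potential, min_separation = 4) {
  pairs <- brute_force_pairs(model, min_separation, potential$grid$cutoff)
  total <- 0; scored <- 0; skipped <- 0
  for (r in seq_len(nrow(pairs))) {
    row <- match(pairs$key[r], rownames(potential$terms))
    if (is.na(row)) { skipped <- skipped + 1; next }
    b <- floor(pairs$distance[r] / potential$grid$bin_width) + 1
    total <- total + potential$terms[row, b]
    scored <- scored + 1
  }
  list(total = unname(total), scored = scored, skipped = skipped)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(model, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  m <- model
  m$atoms$x <- xyz[, 1] + t[1]
  m$atoms$y <- xyz[, 2] + t[2]
  m$atoms$z <- xyz[, 3] + t[3]
  m
}

# small trained potential shared by scoring tests (cached per session)
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corpus <- lapply(1:12, function(i)
        generate_native(60, seed = 500 + i, identifier = paste0("tr", i)))
      ft <- train_frequency_table(corpus, selection = "ca_only")
      cache <<- list(ft = ft, tig = build_potential(ft, "TIG"),
                     pmf = build_potential(ft, "PMF"))
    }
    cache
  }
})
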