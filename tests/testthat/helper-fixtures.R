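# Shared fixtures and independent oracles for the test suite.

# Fixed-column PDB ATOM line builder (independent of the package writer).
pdb_atom_line <- function(serial, name, res, chain, seq, x, y, z,
                          element = substr(name, 1, 1), alt = " ", icode = " ",
                          record = "ATOM  ") {
  nm <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, nm, alt, res, chain, seq, icode, x, y, z, element)
}

write_pdb_lines <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

write_annotation_file <- function(df) {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(df, f)
  f
}

# An ideal helix fitted end to end through the real parser.
fit_ideal <- function(spec) {
  gen <- generate_ideal_helix(spec)
  model <- build_helix_model(group_residues(gen$atoms, gen$annotation),
                             helix_id = spec$helix_id)
  list(gen = gen, model = model)
}

angle_between_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# Independent axis oracle: dense direction search + local refinement that
# maximises the variance of the projections (never touches svd()).
brute_force_axis <- function(M) {
  pv <- function(th, ph) {
    d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    stats::var(as.numeric(M %*% d))
  }
  best <- c(0, 0); bv <- -Inf
  for (th in seq(0, pi, length.out = 60)) {
    for (ph in seq(0, 2 * pi, length.out = 120)) {
      v <- pv(th, ph)
      if (v > bv) { bv <- v; best <- c(th, ph) }
    }
  }
  o <- stats::optim(best, function(p) -pv(p[1], p[2]),
                    control = list(reltol = 1e-14))
  p <- o$par
  c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
}

# Independent Coulomb oracle: naive quadruple loop over helices and sites
# with an inclusion mask, using its own constants.
brute_force_net <- function(sites, eps_r = 1) {
  ke <- 8.9875517873681764e9
  e <- 1.602176634e-19
  ids <- sort(unique(sites$helix_id))
  net <- 0
  for (a in ids) for (b in ids) {
    if (b <= a) next
    sa <- sites[sites$helix_id == a, ]
    sb <- sites[sites$helix_id == b, ]
    for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
      if (sa$charge[i] == 0 || sb$charge[j] == 0) next
      r <- sqrt((sa$x[i] - sb$x[j])^2 + (sa$y[i] - sb$y[j])^2 +
                  (sa$z[i] - sb$z[j])^2) * 1e-10
      net <- net + ke * (sa$charge[i] * e) * (sb$charge[j] * e) / (eps_r * r^2) * 1e12
    }
  }
  net
}

# Seeded random rigid transform.
random_rigid_transform <- function(seed, from = "local", to = "PDB") {
  withr::with_seed(seed, {
    A <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(A)
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    homogeneous_transform(Q, stats::rnorm(3, sd = 5), from, to)
  })
}

# Apply a rigid transform to an atom tibble (x, y, z columns).
transform_atoms <- function(atoms, T) {
  P <- ht_apply(T, cbind(atoms$x, atoms$y, atoms$z))
  atoms$x <- P[, 1]; atoms$y <- P[, 2]; atoms$z <- P[, 3]
  atoms
}

# A seeded random charged bundle built directly as a tidy site table.
random_charge_sites <- function(n_helices, n_residues, seed) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_helices), function(h) {
      tibble::tibble(
        helix_id = h,
        residue_seq = seq_len(n_residues),
        residue_name = sample(c("ASP", "LYS", "ALA"), n_residues, replace = TRUE),
        x = stats::runif(n_residues, 0, 40) + 15 * h,
        y = stats::runif(n_residues, 0, 40),
        z = stats::runif(n_residues, 0, 40),
        charge = sample(c(-1L, 0L, 1L), n_residues, replace = TRUE)
      )
    })
  })
}
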