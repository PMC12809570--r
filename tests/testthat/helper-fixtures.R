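# Shared fixtures: reduced compositions and small synthetic specs keep unit
# tests fast; the full 100-lipid patch is reserved for the acceptance suite.

small_composition <- function() {
  membrane_composition(lipid_definitions(),
                       c(PYPE = 2L, POPE = 1L, YOPE = 2L, PYPG = 2L,
                         POPG = 1L, PVCL2 = 1L))
}

small_spec <- function(condition = "cis", seed = 42, n_frames = 5, ...) {
  synthetic_spec(condition, seed = seed,
                 composition = small_composition(),
                 box = c(30, 30, 80), n_frames = n_frames, ...)
}

# one PYPE lipid as a raw topology table
one_lipid_raw <- function(resname = "PYPE") {
  tpl <- memiso:::lipid_template(lipid_definitions()[[resname]])
  data.frame(resid = 1L, resname = resname, atom = tpl$atoms$atom,
             stringsAsFactors = FALSE)
}

expect_setequal_num <- function(a, b, tol = 1e-8) {
  expect_equal(sort(a), sort(b), tolerance = tol)
}

# R-side brute-force oracle for the grid assignment: full distance matrix
# over every (grid point, atom) pair with explicit xy minimum image.
apl_brute_force <- function(xyz, box, gz, candidates, resid, spacing = 1,
                            use_z = TRUE) {
  nx <- ceiling(box[1] / spacing); ny <- ceiling(box[2] / spacing)
  ax <- box[1] / nx; ay <- box[2] / ny
  gx <- (seq_len(nx) - 0.5) * ax
  gy <- (seq_len(ny) - 0.5) * ay
  grid <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  at <- xyz[candidates, , drop = FALSE]
  win <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    dx <- abs(at[, 1] - grid[g, 1]); dx <- pmin(dx, box[1] - dx)
    dy <- abs(at[, 2] - grid[g, 2]); dy <- pmin(dy, box[2] - dy)
    d2 <- dx^2 + dy^2
    if (use_z) d2 <- d2 + (at[, 3] - gz)^2
    win[g] <- which.min(d2)
  }
  matrix(resid[candidates][win], nx, ny)
}

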