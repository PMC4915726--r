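# fixtures are built in code at test time; nothing binary ships with the
# package

pdb_line <- function(serial, name, res, chain, resnum, x, y, z,
                     occ = 1, b = 0, alt = " ", elem = NULL) {
  if (is.null(elem)) elem <- substr(sub("^[0-9]*", "", name), 1, 1)
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, res, chain, resnum, x, y, z, occ, b, elem)
}

write_pdb_fixture <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# two-residue, two-atom minimal structure
tiny_pdb <- function() {
  write_pdb_fixture(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0)
  ))
}

# synthetic stand-in target sequences (the native sequences are not
# bundled): neutral poly-A background with the wild-type letters planted
# at the positions the edits expect
synth_seq <- function(length, plant) {
  s <- rep("A", length)
  s[as.integer(names(plant))] <- unname(plant)
  paste(s, collapse = "")
}

dera_seq_synthetic <- function() {
  synth_seq(210, c(`18` = "T", `20` = "L", `203` = "A", `204` = "G",
                   `205` = "G", `206` = "K", `207` = "W"))
}

kdpgal_seq_synthetic <- function() {
  synth_seq(60, c(`17` = "V", `18` = "V", `19` = "P", `20` = "V",
                  `21` = "I"))
}

kdpg_seq_synthetic <- function() {
  synth_seq(60, c(`9` = "L", `10` = "I", `11` = "A", `12` = "I",
                  `13` = "L"))
}

# residue-profile builder for divergence fixtures
make_rp <- function(res_num, res_name, mean, sd, chain = "A") {
  out <- data.frame(chain_id = chain, res_num = res_num, ins_code = "",
                    res_name = res_name, mean = mean, sd = sd,
                    n_atoms = 1L, stringsAsFactors = FALSE)
  class(out) <- c("ResidueProfile", "data.frame")
  out
}

make_corr <- function(res_a, res_b, chain = "A") {
  out <- data.frame(chain_a = chain, res_num_a = res_a,
                    chain_b = chain, res_num_b = res_b)
  class(out) <- c("Correspondence", "data.frame")
  out
}

# distance-profile pattern mirroring the published homolog comparison:
# three divergent pairs, glutamates mechanistically excludable
fig_pattern <- function() {
  prof_a <- make_rp(c(10, 12, 37, 100, 154),
                    c("LEU", "ILE", "GLU", "GLY", "VAL"),
                    mean = c(5.0, 3.1, 4.0, 5.5, 3.6),
                    sd = c(0.3, 0.3, 0.3, 0.3, 0.3))
  prof_b <- make_rp(c(18, 20, 45, 108, 161),
                    c("LEU", "VAL", "GLU", "GLY", "THR"),
                    mean = c(5.0, 5.1, 6.0, 5.5, 5.6),
                    sd = c(0.3, 0.3, 0.3, 0.3, 0.3))
  corr <- make_corr(c(10, 12, 37, 100, 154), c(18, 20, 45, 108, 161))
  list(prof_a = prof_a, prof_b = prof_b, corr = corr)
}

# run the full planted-divergence pipeline for one seed; returns the
# candidate pair labels and the planted truth labels
recover_planted <- function(seed, n_residues = 20L,
                            planted = data.frame(res_num = c(4, 9, 15),
                                                 offset = 2.0),
                            sigma = 0.4, n_snap = 1000L) {
  pair <- make_homolog_pair(n_residues = n_residues, planted = planted,
                            seed = seed)
  ens_a <- sample_ensemble(pair$model_a, sigma, n_snap, seed = seed)
  ens_b <- sample_ensemble(pair$model_b, sigma, n_snap, seed = seed + 101L)
  spec_a <- region_spec(center = pair$reference_a, radius = 6,
                        reference_atom = pair$reference_a)
  spec_b <- region_spec(center = pair$reference_b, radius = 6,
                        reference_atom = pair$reference_b)
  rp_a <- aggregate_by_residue(distance_profile(ens_a, spec_a))
  rp_b <- aggregate_by_residue(distance_profile(ens_b, spec_b))
  # structural correspondence seeded by a Kabsch fit of the true CA pairs
  ca_a <- pair$model_a$atoms[pair$model_a$atoms$atom_name == "CA", ]
  ca_b <- pair$model_b$atoms[pair$model_b$atoms$atom_name == "CA", ]
  sup <- kabsch_superpose(cbind(ca_a$x, ca_a$y, ca_a$z),
                          cbind(ca_b$x, ca_b$y, ca_b$z))
  corr <- suppressWarnings(
    build_correspondence(pair$model_a, pair$model_b, sup))
  div <- suppressWarnings(
    divergence_table(rp_a, rp_b, corr, compare_config()))
  list(candidates = sort(as.integer(div$res_num_a[div$candidate])),
       truth = sort(as.integer(planted$res_num)))
}
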