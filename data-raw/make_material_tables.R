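# Generates the packaged photon interaction coefficient tables for CZT and
# water (inst/extdata/coeff_*.txt).
#
# Compton: analytic Klein-Nishina total cross-section per electron times the
# material electron density (exact free-electron theory; binding corrections
# matter only below ~30 keV, well under the energies this package tracks).
# Photoelectric: semi-empirical form mu = A * E^-3 * (1 + E/511), the standard
# E^-3 low-energy fall-off relaxing toward E^-2 above m_e c^2, with A anchored
# per material to well-established attenuation values (CZT photoelectric
# ~0.085 /cm at 511 keV, i.e. a ~17% photofraction; water photoelectric
# ~0.091 /cm at 30 keV).  Rayleigh: mu = B * E^-2 anchored likewise (CZT
# ~0.008 /cm at 511 keV, water ~0.0019 /cm at 100 keV).
# Cross-checks embedded at the bottom: water mu_total(511) ~ 0.096 /cm,
# CZT mu_total(511) ~ 0.51 /cm, CZT mu_total(140) ~ 3 /cm.
#
# Run from the repository root: Rscript data-raw/make_material_tables.R

r_e <- 2.8179403262e-13  # classical electron radius, cm
N_A <- 6.02214076e23
MEC2 <- 511.0

kn_total <- function(E_keV) {
  k <- E_keV / MEC2
  2 * pi * r_e^2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

# electron densities (electrons / cm^3)
ne_water <- 1.000 * N_A * (10 / 18.015)
# Cd0.9 Zn0.1 Te: Z = 0.9*48 + 0.1*30 + 52 = 98.2, M = 235.3 g/mol
ne_czt <- 5.78 * N_A * (98.2 / 235.31)

materials <- list(
  czt = list(
    ne = ne_czt,
    A_pe = 0.085 * 511^3 / (1 + 511 / MEC2),   # anchor: mu_pe(511) = 0.085 /cm
    B_ray = 0.008 * 511^2                      # anchor: mu_ray(511) = 0.008 /cm
  ),
  water = list(
    ne = ne_water,
    A_pe = 0.091 * 30^3 / (1 + 30 / MEC2),     # anchor: mu_pe(30) = 0.091 /cm
    B_ray = 0.0019 * 100^2                     # anchor: mu_ray(100) = 0.0019 /cm
  )
)

E <- exp(seq(log(10), log(1700), length.out = 40))
E <- round(E, 4)

for (nm in names(materials)) {
  m <- materials[[nm]]
  mu_c <- m$ne * kn_total(E)
  mu_pe <- m$A_pe * E^-3 * (1 + E / MEC2)
  mu_r <- m$B_ray * E^-2
  out <- file.path("inst/extdata", sprintf("coeff_%s.txt", nm))
  con <- file(out, "w")
  writeLines(c(
    sprintf("# linear attenuation coefficients for %s (cm^-1)", nm),
    "# generated by data-raw/make_material_tables.R (parametrized model:",
    "#  Klein-Nishina Compton + anchored semi-empirical photoelectric/Rayleigh)",
    "# energy_keV mu_photo mu_compton mu_rayleigh"
  ), con)
  writeLines(sprintf("%.4f %.8e %.8e %.8e", E, mu_pe, mu_c, mu_r), con)
  close(con)
  message("wrote ", out)
}

# sanity anchors
mu_at <- function(m, Eq) {
  c(pe = m$A_pe * Eq^-3 * (1 + Eq / MEC2),
    co = m$ne * kn_total(Eq),
    ra = m$B_ray * Eq^-2)
}
w511 <- sum(mu_at(materials$water, 511)); stopifnot(abs(w511 - 0.096) < 0.01)
c511 <- sum(mu_at(materials$czt, 511));  stopifnot(abs(c511 - 0.51) < 0.05)
c140 <- sum(mu_at(materials$czt, 140));  stopifnot(abs(c140 - 3.1) < 0.6)
message(sprintf("water mu(511)=%.4f  czt mu(511)=%.4f  czt mu(140)=%.4f",
                w511, c511, c140))
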