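# shared fixtures built in code

# coefficients of the reference metabolite release sigmoid
REF_COEFS <- c(a = 0.09805, b = 0.91998, c = 91.1277, d = 22.1166)

# a titration grid spanning the tested 0-400 ug/mL range
WIDE_GRID <- c(5, 25, 50, 75, 100, 150, 200, 300, 400)

# single pure-cytoplasmic probe: both normalization conventions reduce the
# normalized CP series to the release logistic itself
pure_cp_truth <- function(total = 100) {
  make_ground_truth(
    data.frame(analyte = "probe", total_amol_per_cell = total),
    ratio_range = c(0, 0), seed = 1L)
}

# hand-buildable titration table
toy_series <- function(analyte, digitonin, cp, organelle, replicate = 1L) {
  rbind(
    data.frame(analyte = analyte, digitonin_ug_per_ml = digitonin,
               fraction = "CP", replicate = replicate,
               amount_amol_per_cell = cp, stringsAsFactors = FALSE),
    data.frame(analyte = analyte, digitonin_ug_per_ml = digitonin,
               fraction = "organelle", replicate = replicate,
               amount_amol_per_cell = organelle, stringsAsFactors = FALSE))
}

random_release_coefs <- function() {
  c(a = runif(1, 0, 0.3), b = runif(1, 0.5, 1),
    c = runif(1, 30, 300), d = runif(1, 5, 60))
}
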