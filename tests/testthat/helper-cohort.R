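# shared fixtures: compositions and small simulated cohorts

# clinical-style cohort composition: 380 euploid, 65 T21, 30 T18,
# 14 T13, 12 X0 (sex splits balanced where the class allows both)
paper_like_composition <- function() {
  c("46,XX" = 190, "46,XY" = 190,
    "47,XX,+21" = 33, "47,XY,+21" = 32,
    "47,XX,+18" = 15, "47,XY,+18" = 15,
    "47,XX,+13" = 7, "47,XY,+13" = 7,
    "45,X" = 12)
}

# the 13 karyotype states of the caller's vocabulary and their
# expected integrated calls
state_vocabulary <- function() {
  c("46,XX" = "EUPLOID_FEMALE", "46,XY" = "EUPLOID_MALE",
    "47,XY,+13" = "T13", "47,XX,+18" = "T18", "47,XY,+18" = "T18",
    "47,XX,+21" = "T21", "45,X" = "X0", "47,XXX" = "XXX",
    "47,XXY" = "XXY", "47,XYY" = "XYY", "48,XXXY" = "XXXY",
    "69,XXY" = "TRIPLOID_MALE", "69,XYY" = "TRIPLOID_MALE")
}

# noise-free ratio set for a copy-number configuration
ideal_ratios <- function(c13 = 2, c18 = 2, c21 = 2, cX = 2, cY = 0) {
  list(r13 = c13 / c21, r21 = c21 / c13,
       r18X = c18 / cX, rX18 = cX / c18,
       rXY = if (cY > 0) cX / cY else NULL)
}
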