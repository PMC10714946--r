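# Reference anthropometry, organ composition and growth tables.
#
# Values are approximate ICRP/CDC-style reference data written out in code so
# the package carries no external downloads. They are representative, not a
# verbatim copy of any single reference publication; the vignette discusses
# the consequences of this approximation.

# Organs carried by the whole-body model. "rest" lumps remaining perfused
# tissue; "plasma" is split into venous/arterial pools by the engine.
PBPK_ORGANS <- c(
  "adipose", "bone", "brain", "gut", "heart", "kidney",
  "liver", "lung", "muscle", "skin", "spleen", "rest"
)

# Reference adult organ volumes (L, density ~1 kg/L) by sex, chosen so that
# lean volumes + plasma + adipose sum to the reference body weight.
.adult_reference <- list(
  male = list(
    body_weight = 73, height = 176, cardiac_output = 390, hematocrit = 0.44,
    plasma = 3.1,
    volumes = c(
      adipose = 17.0, bone = 10.5, brain = 1.45, gut = 1.65, heart = 0.33,
      kidney = 0.31, liver = 1.80, lung = 0.50, muscle = 29.0, skin = 3.30,
      spleen = 0.15, rest = 3.90
    )
  ),
  female = list(
    body_weight = 60, height = 163, cardiac_output = 330, hematocrit = 0.40,
    plasma = 2.40,
    volumes = c(
      adipose = 18.4, bone = 7.80, brain = 1.30, gut = 1.50, heart = 0.27,
      kidney = 0.28, liver = 1.40, lung = 0.42, muscle = 17.5, skin = 2.30,
      spleen = 0.13, rest = 6.30
    )
  )
)

# Fraction of cardiac output perfusing each organ (sums to 1).
.flow_fractions <- c(
  adipose = 0.050, bone = 0.050, brain = 0.120, gut = 0.150, heart = 0.040,
  kidney = 0.190, liver = 0.065, lung = 0.000, muscle = 0.170, skin = 0.050,
  spleen = 0.030, rest = 0.085
)

# Allometric exponents relating lean organ volume to body weight relative to
# the same-sex adult reference. Brain is nearly mature by age 10.
.organ_weight_exponents <- c(
  adipose = NA_real_, bone = 0.90, brain = 0.05, gut = 1.00, heart = 0.90,
  kidney = 0.85, liver = 0.85, lung = 0.90, muscle = 1.05, skin = 0.90,
  spleen = 0.90, rest = 1.00
)

# Tissue composition used by the partition-coefficient model.
.tissue_water_fraction <- c(
  adipose = 0.15, bone = 0.35, brain = 0.77, gut = 0.75, heart = 0.75,
  kidney = 0.78, liver = 0.72, lung = 0.80, muscle = 0.76, skin = 0.65,
  spleen = 0.78, rest = 0.70
)
.tissue_lipid_fraction <- c(
  adipose = 0.80, bone = 0.05, brain = 0.11, gut = 0.05, heart = 0.06,
  kidney = 0.05, liver = 0.07, lung = 0.03, muscle = 0.03, skin = 0.10,
  spleen = 0.03, rest = 0.05
)

# Median body weight (kg) and height (cm) by age and sex, CDC-style 50th
# percentile through 18 y, then a gentle adult plateau. Linear interpolation
# in between; flat beyond the last row.
.growth_reference <- tibble::tribble(
  ~sex,     ~age, ~weight, ~height,
  "male",     10,    31.9,   138.4,
  "male",     11,    35.8,   143.5,
  "male",     12,    40.6,   149.1,
  "male",     13,    45.8,   156.0,
  "male",     14,    51.0,   163.2,
  "male",     15,    56.0,   169.0,
  "male",     16,    60.8,   172.9,
  "male",     17,    64.4,   175.2,
  "male",     18,    66.9,   176.1,
  "male",     21,    70.0,   176.0,
  "male",     25,    71.5,   176.0,
  "male",     30,    72.0,   176.0,
  "male",     40,    73.0,   176.0,
  "male",     60,    73.0,   175.0,
  "female",   10,    32.9,   138.4,
  "female",   11,    37.0,   144.2,
  "female",   12,    41.5,   150.0,
  "female",   13,    45.8,   155.2,
  "female",   14,    49.4,   158.7,
  "female",   15,    52.0,   161.3,
  "female",   16,    53.9,   162.6,
  "female",   17,    55.1,   163.1,
  "female",   18,    56.7,   163.3,
  "female",   21,    58.5,   163.0,
  "female",   25,    59.5,   163.0,
  "female",   30,    60.0,   163.0,
  "female",   40,    61.0,   163.0,
  "female",   60,    61.0,   162.0
)

# Approximate CDC-style LMS coefficients for BMI-for-age (kg/m^2). The 95th
# percentile derived from these sits within ~0.5 kg/m^2 of the published
# growth-chart curves over 10-18 y, which is adequate for classifying the
# virtual obese population (BMI above the 95th percentile).
.bmi_lms <- tibble::tribble(
  ~sex,     ~age,   ~L,    ~M,    ~S,
  "male",     10, -2.60, 16.60, 0.125,
  "male",     11, -2.50, 17.20, 0.131,
  "male",     12, -2.40, 17.80, 0.135,
  "male",     13, -2.20, 18.50, 0.137,
  "male",     14, -2.00, 19.20, 0.137,
  "male",     15, -1.90, 19.80, 0.135,
  "male",     16, -1.80, 20.40, 0.132,
  "male",     17, -1.70, 20.90, 0.130,
  "male",     18, -1.60, 21.30, 0.128,
  "female",   10, -2.20, 16.70, 0.142,
  "female",   11, -2.10, 17.40, 0.145,
  "female",   12, -2.00, 18.10, 0.146,
  "female",   13, -1.90, 18.80, 0.145,
  "female",   14, -1.85, 19.40, 0.143,
  "female",   15, -1.80, 19.90, 0.140,
  "female",   16, -1.75, 20.30, 0.138,
  "female",   17, -1.70, 20.60, 0.136,
  "female",   18, -1.65, 20.90, 0.135
)

.interp_growth <- function(age, sex) {
  ref <- .growth_reference[.growth_reference$sex == sex, ]
  list(
    weight = stats::approx(ref$age, ref$weight, xout = age, rule = 2)$y,
    height = stats::approx(ref$age, ref$height, xout = age, rule = 2)$y
  )
}

#' BMI percentile curve for age and sex
#'
#' Evaluates the bundled LMS-form BMI-for-age reference (approximate CDC-style
#' coefficients) at a given percentile. Used to classify virtual individuals
#' as obese (BMI above the 95th percentile).
#'
#' @param age Age in years (10-18; clamped to the table range).
#' @param sex `"female"` or `"male"`.
#' @param percentile Percentile in (0, 100); default 95.
#' @return BMI in kg/m^2 at the requested percentile.
#' @export
#' @examples
#' bmi_percentile(12, "female")
bmi_percentile <- function(age, sex, percentile = 95) {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(percentile > 0, percentile < 100)
  ref <- .bmi_lms[.bmi_lms$sex == sex, ]
  L <- stats::approx(ref$age, ref$L, xout = age, rule = 2)$y
  M <- stats::approx(ref$age, ref$M, xout = age, rule = 2)$y
  S <- stats::approx(ref$age, ref$S, xout = age, rule = 2)$y
  z <- stats::qnorm(percentile / 100)
  M * (1 + L * S * z)^(1 / L)
}

# Body surface area (m^2), Du Bois formula.
.bsa <- function(weight_kg, height_cm) {
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

# Absolute GFR (mL/min) from a BSA-normalised reference of 120 mL/min/1.73 m^2;
# maturation is adult-like from age 10 so no ontogeny function is applied.
.gfr_from_bsa <- function(weight_kg, height_cm) {
  120 * .bsa(weight_kg, height_cm) / 1.73
}

# Tissue water fraction is modestly higher before adulthood; linear fade from
# +8 % at age 10 to the adult value at 18.
.water_age_factor <- function(age) {
  if (age >= 18) 1 else 1 + 0.08 * (18 - age) / 8
}
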