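# Build inst/extdata/ise_{male,female}.json from the published coefficients
# (run from the repo root with pkgload).
pkgload::load_all(".", quiet = TRUE)

pm <- function(link, int, blh = 0, bla = 0, spl = FALSE)
  parameter_model(link, int, blh, bla, spline = NULL, spline_declared = spl)

male <- equation_set(
  name = "ISE-male", sex = "male",
  splines_omitted_acknowledged = TRUE,
  indices = list(
    fev1 = list(family = "BCCG",
      mu = pm("identity", -28.1570, 6.8055, -0.8566, spl = TRUE),
      sigma = pm("log", -1.8308, 0, -0.1192, spl = TRUE),
      nu = pm("identity", -2.3096, 0, 0.3956)),
    fvc = list(family = "BCCG",
      mu = pm("log", -8.37157, 2.05757, -0.20888),
      sigma = pm("log", -2.14143),
      nu = pm("identity", -1.8044)),
    fev1_fvc = list(family = "BCCG",
      mu = pm("identity", 1.458485, -0.111511, -0.007171, spl = TRUE),
      sigma = pm("log", -3.39125, 0, 0.15846, spl = TRUE),
      nu = pm("identity", 0.4028, 0, -0.4593)),
    fef2575 = list(family = "BCCG",
      mu = pm("log", -4.20476, 1.23963, -0.20600, spl = TRUE),
      sigma = pm("log", -2.42013, 0, 0.18673, spl = TRUE),
      nu = pm("identity", -4.8567, 0, 1.0254))))

female <- equation_set(
  name = "ISE-female", sex = "female",
  splines_omitted_acknowledged = TRUE,
  indices = list(
    fev1 = list(family = "BCCG",
      mu = pm("identity", -24.46931, 5.85935, -0.65217, spl = TRUE),
      sigma = pm("log", -2.8156, 0, 0.1647, spl = TRUE),
      nu = pm("identity", -2.2930, 0, 0.2341)),
    fvc = list(family = "BCCG",
      mu = pm("log", -11.26749, 2.61061, -0.22545),
      sigma = pm("log", -2.08730),
      nu = pm("identity", -1.8645)),
    fev1_fvc = list(family = "BCCG",
      mu = pm("log", 1.968086, -0.416269, 0.009565, spl = TRUE),
      sigma = pm("log", -3.7224, 0, 0.3145, spl = TRUE),
      nu = pm("identity", 1)),
    fef2575 = list(family = "BCPE",
      mu = pm("log", -3.5388, 1.0490, -0.1505, spl = TRUE),
      sigma = pm("log", -3.9378, 0, 0.6482, spl = TRUE),
      nu = pm("identity", -7.711, 0, 1.956),
      tau = pm("log", 0.6736, 0, 0.637))))

save_equation_set(male, "./inst/extdata/ise_male.json")
save_equation_set(female, "./inst/extdata/ise_female.json")
cat("wrote ISE JSON files\n")
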