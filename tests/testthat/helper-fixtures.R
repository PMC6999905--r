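# shared across test files

fx_all <- nof1_fixtures()
fx_1390 <- fx_all$patient_1390
fib_patients <- setdiff(names(fx_all), "patient_1390")

# rho grid used by the property sweeps
rho_grid <- c(-0.9, -0.5, -0.33, -0.1, 0, 0.1, 0.33, 0.5, 0.67, 0.9)

# round half away from zero, as printed tables do
rhu <- function(x, digits = 2) sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
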