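# Example generator configuration: a scaled-down register with 20
# maternal countries of birth. Every omitted field keeps the package's
# published-study default (variance components, covariate frequencies,
# gestational-age distribution, parity mix).
n_countries: 20
n_mothers: 2000
dominant_country_share: 0.6
country_size_concentration: 1.0
seed: 42
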