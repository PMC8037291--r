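# Magnetic-flux-density exposure limit curves, transcribed row-for-row from
# the regulatory tables (B column only; other columns kept as unparsed notes).
#
#   RL_B      Recommendation 1999/519/EC reference levels, general public
#   LOW_AL_B  Directive 2013/35/EU low action levels (sensory-effect ELVs)
#   HIGH_AL_B Directive 2013/35/EU high action levels (health-effect ELVs)
#   LIMB_AL_B Directive 2013/35/EU action levels for localised limb exposure
#
# All values are RMS microtesla. f_lo / f_hi are in Hz, lower-inclusive /
# upper-exclusive (terminal segment upper-inclusive). `freq_unit` is the unit
# in which f enters the printed formula for that row (Hz, kHz or MHz), so the
# coefficients below match the source tables verbatim.
# form: constant -> c ; c_over_f -> c/f ; c_over_f2 -> c/f^2 ; c_sqrt_f -> c*sqrt(f)
version: "EU-limit-tables 1.0 (2013/35/EU Table AL-B; 1999/519/EC Table RL)"
curves:
  LOW_AL_B:
    source: "Directive 2013/35/EU, low action levels for magnetic flux density, 1 Hz - 10 MHz"
    value_convention: RMS
    segments:
      - {f_lo: 1, f_hi: 8, form: c_over_f2, coefficient: 200000, freq_unit: Hz}
      - {f_lo: 8, f_hi: 25, form: c_over_f, coefficient: 25000, freq_unit: Hz}
      - {f_lo: 25, f_hi: 300, form: constant, coefficient: 1000, freq_unit: Hz}
      - {f_lo: 300, f_hi: 3000, form: c_over_f, coefficient: 300000, freq_unit: Hz}
      - {f_lo: 3000, f_hi: 10000000, form: constant, coefficient: 100, freq_unit: Hz}
  HIGH_AL_B:
    source: "Directive 2013/35/EU, high action levels for magnetic flux density, 1 Hz - 10 MHz"
    value_convention: RMS
    segments:
      - {f_lo: 1, f_hi: 8, form: c_over_f, coefficient: 300000, freq_unit: Hz}
      - {f_lo: 8, f_hi: 25, form: c_over_f, coefficient: 300000, freq_unit: Hz}
      - {f_lo: 25, f_hi: 300, form: c_over_f, coefficient: 300000, freq_unit: Hz}
      - {f_lo: 300, f_hi: 3000, form: c_over_f, coefficient: 300000, freq_unit: Hz}
      - {f_lo: 3000, f_hi: 10000000, form: constant, coefficient: 100, freq_unit: Hz}
  LIMB_AL_B:
    source: "Directive 2013/35/EU, action levels for exposure of limbs to a localised magnetic field, 1 Hz - 10 MHz"
    value_convention: RMS
    segments:
      - {f_lo: 1, f_hi: 8, form: c_over_f, coefficient: 900000, freq_unit: Hz}
      - {f_lo: 8, f_hi: 25, form: c_over_f, coefficient: 900000, freq_unit: Hz}
      - {f_lo: 25, f_hi: 300, form: c_over_f, coefficient: 900000, freq_unit: Hz}
      - {f_lo: 300, f_hi: 3000, form: c_over_f, coefficient: 900000, freq_unit: Hz}
      - {f_lo: 3000, f_hi: 10000000, form: constant, coefficient: 300, freq_unit: Hz}
  RL_B:
    source: "Recommendation 1999/519/EC, reference levels (unperturbed RMS), B column, 0 Hz - 300 GHz"
    value_convention: RMS
    segments:
      - {f_lo: 0, f_hi: 1, form: constant, coefficient: 40000, freq_unit: Hz,
         notes: "H 3.2e4 A/m; E -"}
      - {f_lo: 1, f_hi: 8, form: c_over_f2, coefficient: 40000, freq_unit: Hz,
         notes: "H 3.2e4/f^2 A/m; E 10000 V/m"}
      - {f_lo: 8, f_hi: 25, form: c_over_f, coefficient: 5000, freq_unit: Hz,
         notes: "H 4000/f A/m; E 10000 V/m"}
      - {f_lo: 25, f_hi: 800, form: c_over_f, coefficient: 5, freq_unit: kHz,
         notes: "range printed 0.025-0.8 kHz; H 4/f A/m; E 250/f V/m"}
      - {f_lo: 800, f_hi: 3000, form: constant, coefficient: 6.25, freq_unit: kHz,
         notes: "range printed 0.8-3 kHz; H 5 A/m; E 250/f V/m"}
      - {f_lo: 3000, f_hi: 150000, form: constant, coefficient: 6.25, freq_unit: kHz,
         notes: "range printed 3-150 kHz; H 5 A/m; E 87 V/m"}
      - {f_lo: 150000, f_hi: 1000000, form: c_over_f, coefficient: 0.92, freq_unit: MHz,
         notes: "range printed 0.15-1 MHz; H 0.73/f A/m; E 87 V/m"}
      - {f_lo: 1000000, f_hi: 10000000, form: c_over_f, coefficient: 0.92, freq_unit: MHz,
         notes: "range printed 1-10 MHz; H 0.73/f A/m; E 87/sqrt(f) V/m"}
      - {f_lo: 10000000, f_hi: 400000000.0, form: constant, coefficient: 0.092, freq_unit: MHz,
         notes: "range printed 10-400 MHz; H 0.073 A/m; E 28 V/m; S 2 W/m^2"}
      - {f_lo: 400000000.0, f_hi: 2000000000.0, form: c_sqrt_f, coefficient: 0.0046, freq_unit: MHz,
         notes: "range printed 400-2000 MHz; H 0.0037*sqrt(f) A/m; E 1.375*sqrt(f) V/m; S f/200 W/m^2"}
      - {f_lo: 2000000000.0, f_hi: 300000000000.0, form: constant, coefficient: 0.20, freq_unit: GHz,
         notes: "range printed 2-300 GHz; H 0.16 A/m; E 61 V/m; S 10 W/m^2"}
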