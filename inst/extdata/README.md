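# Bundled example data

- `screening_synthetic.tsv` — a *synthetic* virus screening table (353
  larvae across six regional populations, 39 positives; within-population
  infection frequency spanning ~3-52%). It is generated to match the
  marginal structure of a continent-wide inherited-virus screen and is
  used by the examples, tests, and the acceptance script; it is not real
  screening data.
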