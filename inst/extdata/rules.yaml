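# Clinical inference rules in the declarative rule-file syntax. Predicates
# may use English names; they are resolved to the canonical local names
# through the alias map.
rules:
  - name: BodyMassIndex
    body:
      - "dato:hasWeight(?n, ?p)"
      - "dato:hasHeight(?n, ?t)"
      - "swrlb:multiply(?t2, ?t, ?t)"
      - "swrlb:divide(?imc, ?p, ?t2)"
    head:
      - "dato:hasBMI(?n, ?imc)"
  - name: WaistHipIndex
    body:
      - "dato:hasWaistMeasure(?n, ?ci)"
      - "dato:hasHipMeasure(?n, ?ca)"
      - "swrlb:divide(?icc, ?ci, ?ca)"
    head:
      - "dato:hasWHI(?n, ?icc)"
  - name: OverweightFunction
    body:
      - "dato:hasBMI(?n, ?imc)"
      - "swrlb:greaterThanOrEqual(?imc, 25)"
      - "swrlb:lessThan(?imc, 30)"
    head:
      - "dato:hasHumanBiotype(?n, dato:Overweight)"
  - name: BasalMetabolicRateFemaleOver60
    body:
      - "per:hasGender(?pa, ?sx)"
      - 'swrlb:stringEqualIgnoreCase(?sx, "Female")'
      - "red:hasClinicalRecord(?pa, ?ec)"
      - "dato:hasMedicalNote(?ec, ?nm)"
      - "dato:hasAge(?nm, ?e)"
      - "swrlb:greaterThanOrEqual(?e, 61)"
      - "dato:hasWeight(?nm, ?p)"
      - "swrlb:multiply(?aux, 10.5, ?p)"
      - "swrlb:add(?tasa, ?aux, 596)"
    head:
      - "dato:hasBMR(?nm, ?tasa)"
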