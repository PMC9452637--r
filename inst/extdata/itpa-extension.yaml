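# Declarative extension document: the ITPA scenario for the thiopurine CDS
# demo (same content as polykb::build_itpa_extension()). Apply with
#   Rscript <cli> --session cds.yaml extend --spec itpa-extension.yaml
table:
  name: ITPATherapy
  fields:
  - name: specification
    type: TEXT
    annotation: therapy specification informed by the ITPA genotype
    constraints:
    - kind: required
records:
- specification: Adjust thiopurine therapy for patients carrying a deficient ITPA genotype per the new evidence.
rewires:
- table: Judgement
  id: 3
  field: Next
  target_table: ITPATherapy
  target_id: 1
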