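{
  "name": "default_channel_synthetic",
  "description": "SYNTHETIC stand-in profile. Components: column-synthesized oligos with ErrASE error correction, Illumina single-end sequencing, PCR with Taq for 30 cycles, storage in E. coli for 24 months. Only the total per-base error rate of 0.33% is a published quantity; the per-component split and type patterns below are constructed placeholders chosen to be of realistic relative magnitude, and are documented as such.",
  "error_sources": [
    {
      "name": "synthesis: column synthesis + ErrASE",
      "rate": 0.00105,
      "pattern": {"substitution": 0.55, "insertion": 0.20, "deletion": 0.25}
    },
    {
      "name": "sequencing: Illumina single-end",
      "rate": 0.00180,
      "pattern": {"substitution": 0.90, "insertion": 0.05, "deletion": 0.05}
    },
    {
      "name": "PCR: Taq, 30 cycles",
      "rate": 0.00036,
      "pattern": {"substitution": 0.95, "insertion": 0.025, "deletion": 0.025}
    },
    {
      "name": "storage: E. coli, 24 months",
      "rate": 0.00009,
      "pattern": {"substitution": 0.50, "insertion": 0.25, "deletion": 0.25}
    }
  ],
  "amplifier_total": null
}
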