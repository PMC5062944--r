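{
  "title": "genocrypt metrics report",
  "required": {
    "task": "string",
    "accuracy_exact": "boolean",
    "max_deviation": "number",
    "security_bits": "number",
    "storage_bytes": "number",
    "comm_bytes_total": "number",
    "time_s": "object",
    "comm_bytes": "object",
    "config_hash": "string"
  }
}
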