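Alternative prompt style: direct question (prefix). Provided for
experimentation; the default pipeline uses the zero-shot answer template.

Did this patient with breast cancer have access to germline genetic testing
(Yes, No, Not applicable, or Not sure)? Answer on one line starting with
"ANSWER:".

Clinical note excerpts:
{{document}}
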