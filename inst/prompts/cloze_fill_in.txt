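Alternative prompt style: cloze (fill in the blank). Provided for
experimentation; the default pipeline uses the zero-shot answer template.

Clinical note excerpts:
{{document}}

Considering the categories Yes, No, Not applicable, and Not sure, the
patient's access to germline genetic testing is best described as
ANSWER: ____
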