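label_1,label_2,wrist_extension,ulnar_deviation,finger_flexion,wrist_flexion,off_state,inferred
High_N,High_N,High,Low,Low,Low,Low,FALSE
High_N,Low_N,Med,Low,Low,Low,Low,FALSE
High_N,Off,Low,Low,Low,Low,Low,FALSE
High_N,Low,Low,Low,Low,Low,Low,TRUE
High_N,Med,Low,Low,Low,Low,Low,TRUE
High_N,High,Low,Low,Low,Low,Low,TRUE
Low_N,High_N,Med,Low,Low,Low,Low,FALSE
Low_N,Low_N,Med,Low,Low,Low,Med,FALSE
Low_N,Off,Low,Low,Low,Low,Med,FALSE
Low_N,Low,Low,Low,Low,Low,Low,TRUE
Low_N,Med,Low,Low,Low,Low,Low,TRUE
Low_N,High,Low,Low,Low,Low,Low,TRUE
Off,High_N,Low,Low,Low,Low,Low,FALSE
Off,Low_N,Low,Low,Low,Low,Med,FALSE
Off,Off,Low,Low,Low,Low,High,FALSE
Off,Low,Low,High,Low,Low,Med,TRUE
Off,Med,Low,Low,Low,Low,Low,TRUE
Off,High,Low,Low,Low,Low,Low,TRUE
Low,High_N,Low,Low,Low,Low,Low,TRUE
Low,Low_N,Low,Low,Low,Low,Low,TRUE
Low,Off,Low,High,Low,Low,Med,FALSE
Low,Low,Low,Med,Low,Low,Med,FALSE
Low,Med,Low,Low,Low,Low,Low,FALSE
Low,High,Low,Low,Low,Low,Low,TRUE
Med,High_N,Low,Low,Low,Low,Low,TRUE
Med,Low_N,Low,Low,Low,Low,Low,TRUE
Med,Off,Low,Low,Low,Low,Low,TRUE
Med,Low,Low,Med,Low,Low,Low,FALSE
Med,Med,Low,Low,Med,Low,Low,FALSE
Med,High,Low,Low,High,Low,Low,FALSE
High,High_N,Low,Low,Low,Low,Low,TRUE
High,Low_N,Low,Low,Low,Low,Low,TRUE
High,Off,Low,Low,Low,Low,Low,TRUE
High,Low,Low,Low,Low,Low,Low,FALSE
High,Med,Low,Low,Med,Med,Low,FALSE
High,High,Low,Low,Low,High,Low,FALSE
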