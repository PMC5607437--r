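"test","domain","mean","sd","direction"
"letter_number_sequencing","working_memory",10.5,2.5,1
"digit_span_backward","working_memory",4.8,1.2,1
"digit_span_forward","attention_processing_speed",6.6,1.1,1
"digit_symbol","attention_processing_speed",45,11,1
"trail_making_a","attention_processing_speed",42,15,-1
"logical_memory_ii","memory",12.5,4,1
"visual_reproduction_ii","memory",15.5,6.5,1
"word_list_recall","memory",6.8,1.8,1
"letter_fluency_cfl","executive_function",38,11,1
"trail_making_b","executive_function",105,45,-1
"stroop","executive_function",28,7.5,1
"block_design","visuospatial",25,7,1
"picture_completion","visuospatial",14,3.5,1
"visual_reproduction_i","visuospatial",27,7,1
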