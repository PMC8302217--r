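gene	is_ig	de_class
Pcdhb1	FALSE	NE
Pcdhb2	FALSE	NC
Pcdhb3	TRUE	UP
Pcdhb4	TRUE	UP
Pcdhb5	FALSE	NC
Pcdhb6	FALSE	NC
Pcdhb7	TRUE	UP
Pcdhb8	TRUE	NC
Pcdhb9	TRUE	NC
Pcdhb10	TRUE	UP
Pcdhb11	TRUE	UP
Pcdhb12	TRUE	NC
Pcdhb13	TRUE	NC
Pcdhb14	TRUE	NC
Pcdhb15	TRUE	NC
Pcdhb16	TRUE	NC
Pcdhb17	TRUE	UP
Pcdhb18	TRUE	NC
Pcdhb19	TRUE	UP
Pcdhb20	TRUE	UP
Pcdhb21	TRUE	UP
Pcdhb22	TRUE	NC
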