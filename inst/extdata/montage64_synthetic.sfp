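Fpz	0	85	5.20474889637625e-15
AFz	0	80.839803885088	26.2664445218705
Fz	0	68.7664445218705	49.9617464448602
FCz	0	49.9617464448602	68.7664445218705
Cz	0	0	85
CPz	0	-49.9617464448602	68.7664445218705
Pz	0	-68.7664445218705	49.9617464448602
POz	0	-80.839803885088	26.2664445218705
Oz	0	-85	5.20474889637625e-15
Iz	0	-80.8398038850881	-26.2664445218705
Fp1	-26.2664445218705	80.839803885088	4.95001035357864e-15
Fp2	26.2664445218705	80.839803885088	4.95001035357864e-15
AF7	-65.1137776651131	51.9628243068244	16.8837450891773
AF3	-29.0717121826818	75.9645671765973	24.6823840914842
AF8	65.1137776651131	51.9628243068244	16.8837450891773
AF4	29.0717121826818	75.9645671765973	24.6823840914842
F7	-70.4681936671786	38.4537077735448	27.9382540569706
F5	-56.876101540503	51.1034274129064	37.1288133423115
F3	-39.9050828368007	60.7171666600525	44.1136037585174
F1	-20.5633611259718	66.7237872307664	48.4776690527328
F8	70.4681936671786	38.4537077735448	27.9382540569706
F6	56.876101540503	51.1034274129064	37.1288133423115
F4	39.9050828368007	60.7171666600525	44.1136037585174
F2	20.5633611259718	66.7237872307664	48.4776690527328
FT7	-79.8738727668022	13.1982811421	25.903085224096
FC5	-56.876101540503	28.6773587092739	56.2824854729607
FC3	-39.9050828368007	34.0722346086976	66.8705255890661
FC1	-20.5633611259718	37.4429285417108	73.4858849128403
FT8	79.8738727668022	13.1982811421	25.903085224096
FC6	56.876101540503	28.6773587092739	56.2824854729607
FC4	39.9050828368007	34.0722346086976	66.8705255890661
FC2	20.5633611259718	37.4429285417108	73.4858849128403
T7	-85	0	5.20474889637625e-15
C5	-56.876101540503	0	63.1673101655785
C3	-39.9050828368007	0	75.0505453930088
C1	-20.5633611259718	0	82.4751367334597
T8	85	0	5.20474889637625e-15
C6	56.876101540503	0	63.1673101655785
C4	39.9050828368007	0	75.0505453930088
C2	20.5633611259718	0	82.4751367334597
TP7	-79.8738727668022	-13.1982811421	25.903085224096
CP5	-56.876101540503	-28.6773587092739	56.2824854729607
CP3	-39.9050828368007	-34.0722346086976	66.8705255890661
CP1	-20.5633611259718	-37.4429285417108	73.4858849128403
TP8	79.8738727668022	-13.1982811421	25.903085224096
CP6	56.876101540503	-28.6773587092739	56.2824854729607
CP4	39.9050828368007	-34.0722346086976	66.8705255890661
CP2	20.5633611259718	-37.4429285417108	73.4858849128403
P9	-83.1425460623735	-14.2973477520678	10.3876311795591
P7	-70.4681936671786	-38.4537077735448	27.9382540569706
P5	-56.876101540503	-51.1034274129064	37.1288133423115
P3	-39.9050828368007	-60.7171666600525	44.1136037585174
P1	-20.5633611259718	-66.7237872307664	48.4776690527328
P10	83.1425460623735	-14.2973477520678	10.3876311795591
P8	70.4681936671786	-38.4537077735448	27.9382540569706
P6	56.876101540503	-51.1034274129064	37.1288133423115
P4	39.9050828368007	-60.7171666600525	44.1136037585174
P2	20.5633611259718	-66.7237872307664	48.4776690527328
PO7	-65.1137776651131	-51.9628243068244	16.8837450891773
PO3	-29.0717121826818	-75.9645671765973	24.6823840914842
PO8	65.1137776651131	-51.9628243068244	16.8837450891773
PO4	29.0717121826818	-75.9645671765973	24.6823840914842
O1	-26.2664445218705	-80.839803885088	4.95001035357864e-15
O2	26.2664445218705	-80.839803885088	4.95001035357864e-15
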