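   SW   perc perc perc  query     position in query              matching  repeat         position in repeat
score   div. del. ins.  sequence  begin  end          (left)    repeat     class/family      begin  end    (left)  ID

  463   21.5  0.6  1.7  chr1       1001   1100        (18900)   +  Rex3      LINE/Rex-Babar      62   161     (0)    1
  312    8.2  0.0  0.3  chr1       5001   5400        (14600)   C  hAT-7     DNA/hAT             12   411    (20)    2
  198    2.0  0.0  0.0  chr2        201    480         (9520)   +  TcMar4    DNA/Tc-Mariner       1   280   (100)    3
   95   45.0  2.1  1.9  chr2        900    955         (9045)   +  Copia1    LTR/Copia           30    85    (15)    4
  120   12.0  0.0  0.0  chr2       3001   3070         (6930)   +  SimpleRep Unknown              1    70     (0)    5
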