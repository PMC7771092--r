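a
about
above
after
again
against
all
also
although
am
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
can
could
did
do
does
doing
don
down
during
each
few
for
from
further
had
has
have
having
he
her
here
him
his
how
i
if
in
into
is
it
its
just
may
me
might
more
most
must
my
no
nor
not
of
off
on
only
or
other
our
out
over
own
s
same
shall
she
should
so
some
such
t
than
that
the
their
them
then
there
these
they
this
those
though
through
to
too
under
up
us
very
was
we
were
what
when
where
which
while
who
whom
why
will
with
would
yet
you
your
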